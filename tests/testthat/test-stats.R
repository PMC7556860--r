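# construct x, y with an exactly specified correlation
make_corr_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  z <- stats::rnorm(n)
  z <- stats::residuals(stats::lm(z ~ x))
  x <- as.numeric(scale(x)); z <- as.numeric(scale(z))
  list(x = x, y = r * x + sqrt(1 - r^2) * z)
}

test_that("pearson_ci: exact cases, one-tailed p, and the Fisher-z interval", {
  x <- 1:10
  expect_equal(pearson_ci(x, x * 2 + 1)$r, 1, tolerance = 1e-12)
  expect_error(pearson_ci(x, rep(1, 10)), "zero variance")

  # r = -0.685 with n = 55 must give the 95% CI [-0.804, -0.513]
  d <- make_corr_pair(55, -0.685)
  cr <- pearson_ci(d$x, d$y, tail = "negative")
  expect_equal(cr$r, -0.685, tolerance = 1e-12)
  expect_equal(round(cr$ci95, 3), c(-0.804, -0.513))
  expect_lt(cr$p_raw, 1e-4)

  # one-tailed p agrees with cor.test in both directions
  set.seed(2)
  a <- stats::rnorm(30); b <- a + stats::rnorm(30, 0, 2)
  expect_equal(pearson_ci(a, b, "positive")$p_raw,
               stats::cor.test(a, b, alternative = "greater")$p.value)
  expect_equal(pearson_ci(a, b, "negative")$p_raw,
               stats::cor.test(a, b, alternative = "less")$p.value)
  expect_equal(pearson_ci(a, b, "two")$ci95,
               stats::cor.test(a, b)$conf.int, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("one-tailed p agrees with a permutation oracle on a small sample", {
  set.seed(31)
  x <- stats::rnorm(20)
  y <- 0.5 * x + stats::rnorm(20)
  r_obs <- stats::cor(x, y)
  nperm <- 10000
  perm <- replicate(nperm, stats::cor(x, sample(y)))
  p_perm <- (sum(perm >= r_obs) + 1) / (nperm + 1)
  p_t <- pearson_ci(x, y, "positive")$p_raw
  se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(p_t - p_perm), 4 * se + 0.005)
})

test_that("Holm adjustment is step-down with monotonicity, idempotent, and tie-safe", {
  expect_equal(holm_adjust(0.03), 0.03)
  # step-down with cummax on the sorted family {.005,.01,.03,.04}
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.03, 0.06, 0.06, 0.02))
  expect_equal(holm_adjust(rep(0.3, 4)), rep(1, 4))   # ties, capped at 1
  p <- c(0.001, 0.2, 0.04, 0.9)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_equal(order(adj), order(p))                  # rank-monotone
  expect_error(holm_adjust(numeric(0)), "empty")
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("partial correlation matches the precision-matrix formula and reduces cleanly", {
  set.seed(4)
  n <- 80
  Z <- matrix(stats::rnorm(n * 4), n, 4)
  x <- Z %*% c(1, -0.5, 0.2, 0) + stats::rnorm(n)
  y <- Z %*% c(0.3, 0.4, -1, 0.5) + 0.5 * x + stats::rnorm(n)
  pc <- partial_correlation(as.numeric(x), as.numeric(y), as.data.frame(Z))
  # precision-matrix oracle on the 6-variable system
  S <- stats::cov(cbind(x, y, Z))
  P <- solve(S)
  r_prec <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  expect_equal(pc$r, r_prec, tolerance = 1e-10)

  # empty covariate set reduces to pearson_ci
  p0 <- partial_correlation(as.numeric(x), as.numeric(y), NULL, tail = "positive")
  p1 <- pearson_ci(as.numeric(x), as.numeric(y), tail = "positive")
  expect_equal(p0$r, p1$r)
  expect_equal(p0$p_raw, p1$p_raw)

  # covariates unrelated to x and y leave r near the zero-order value
  set.seed(5)
  W <- as.data.frame(matrix(stats::rnorm(n * 3), n, 3))
  a <- stats::rnorm(n); b <- 0.6 * a + stats::rnorm(n)
  expect_equal(partial_correlation(a, b, W)$r, stats::cor(a, b),
               tolerance = 0.1)

  # partial df/CI match the published convention (r_p = -0.364, n = 55,
  # k = 3 -> CI [-0.58, -0.101])
  ci <- tanh(atanh(-0.364) + c(-1, 1) * stats::qnorm(.975) / sqrt(55 - 3 - 3))
  expect_equal(ci, c(-0.580, -0.101), tolerance = 2e-3)

  expect_error(partial_correlation(a, b, data.frame(u = W[, 1], v = W[, 1])),
               "rank|collinear")
})

test_that("Steiger's Z: null case, antisymmetry, and a dual-formula cross-check", {
  expect_equal(steiger_z(0.5, 0.5, 0.3, 50)$z, 0)
  z1 <- steiger_z(0.7, 0.4, 0.5, 60)
  z2 <- steiger_z(0.4, 0.7, 0.5, 60)
  expect_equal(z1$z, -z2$z, tolerance = 1e-12)

  # independent implementation from the covariance (psi) form of the
  # pooled-correlation statistic
  steiger_psi <- function(rjk, rjh, rkh, n) {
    rb <- (rjk + rjh) / 2
    psi <- rkh * (1 - rb^2 - rb^2) - 0.5 * (rb * rb) *
      (1 - rb^2 - rb^2 - rkh^2)
    cbar <- psi / (1 - rb^2)^2
    sqrt(n - 3) * (atanh(rjk) - atanh(rjh)) / sqrt(2 - 2 * cbar)
  }
  set.seed(8)
  for (i in 1:50) {
    # draw a valid (positive-definite) correlation triple
    repeat {
      r <- stats::runif(3, -0.9, 0.9)
      M <- matrix(c(1, r[1], r[2], r[1], 1, r[3], r[2], r[3], 1), 3)
      if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) > 0.01)
        break
    }
    expect_equal(steiger_z(r[1], r[2], r[3], 40)$z,
                 steiger_psi(r[1], r[2], r[3], 40), tolerance = 1e-8)
  }
  expect_error(steiger_z(1, 0.5, 0.3, 50), "degenerate")
})

test_that("hierarchical OLS decomposes variance consistently", {
  set.seed(6)
  n <- 100
  # orthogonal predictors (also orthogonal to the intercept): increments
  # equal marginal R2 in any order
  Q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n * 3), n, 3))))[, -1]
  X <- as.data.frame(Q); names(X) <- c("a", "b", "c")
  y <- 2 * X$a - 1 * X$b + 0.5 * X$c + stats::rnorm(n, 0, 0.5)
  h1 <- hierarchical_ols(y, X)
  h2 <- hierarchical_ols(y, X[c("c", "a", "b")])
  marg <- sapply(X, function(v) stats::cor(y, v)^2)
  expect_equal(unname(h1$incremental_R2), unname(marg[c("a", "b", "c")]),
               tolerance = 1e-10)
  expect_equal(h1$full_R2, h2$full_R2, tolerance = 1e-12)

  # correlated predictors: first increment = squared zero-order correlation;
  # increments sum to the full-model R2 to 1e-12
  set.seed(7)
  W <- as.data.frame(matrix(stats::rnorm(n * 4), n, 4))
  W$V2 <- W$V1 * 0.8 + W$V2 * 0.6
  yw <- W$V1 + W$V2 + stats::rnorm(n)
  hw <- hierarchical_ols(yw, W)
  expect_equal(unname(hw$incremental_R2[1]), stats::cor(yw, W$V1)^2,
               tolerance = 1e-12)
  expect_equal(sum(hw$incremental_R2), hw$full_R2, tolerance = 1e-12)
  expect_equal(hw$full_R2, summary(stats::lm(yw ~ ., data = W))$r.squared,
               tolerance = 1e-12)
  expect_true(all(hw$vif >= 1))

  # rank deficiency names the offending predictor
  Wb <- W; Wb$dup <- Wb$V1
  expect_error(hierarchical_ols(yw, Wb), "dup")
})

test_that("bootstrap test-retest: exact noiseless limit and pure-noise limit", {
  scheme <- data.frame(subject = sprintf("S%d", 1:30),
                       mean = stats::rnorm(30, 0, 5), sd = 0)
  expect_identical(bootstrap_test_retest(scheme, "modulation",
                                         iterations = 50)$r, 1)

  set.seed(12)
  noisy <- data.frame(subject = sprintf("S%d", 1:30),
                      mean = stats::rnorm(30, 0, 0.01), sd = 5)
  r0 <- bootstrap_test_retest(noisy, "modulation", iterations = 2000)$r
  expect_lt(abs(r0), 0.05)
})

test_that("bootstrap reliability decreases monotonically with within-subject noise", {
  set.seed(13)
  mu <- stats::rnorm(40, 0, 5)
  rs <- sapply(c(1, 3, 6, 12), function(ws) {
    set.seed(100 + ws)
    bootstrap_test_retest(
      data.frame(subject = seq_along(mu), mean = mu, sd = ws),
      "modulation", iterations = 2000)$r
  })
  expect_true(all(diff(rs) < 0))
})

test_that("masking-slope bootstrap reproduces regression-based reliability", {
  set.seed(14)
  n <- 30
  f <- pip_frequencies()
  lows <- stats::rnorm(n, 50, 20)
  highs <- stats::rnorm(n, -25, 10)
  scheme <- do.call(rbind, lapply(1:n, function(i) {
    pat <- ifelse(f < 1000, 60 + lows[i] * log2(f / 1000),
                  60 + highs[i] * log2(f / 1000))
    data.frame(subject = i, pip_freq = f, mean = pat, sd = 2)
  }))
  out <- bootstrap_test_retest(scheme, "masking-slopes", iterations = 2000)
  # closed-form reliability: BS^2 / (BS^2 + slope-noise variance), with the
  # slope noise propagated from 2-run phase means (sd 2) through the fixed
  # regression design
  slope_var <- function(xs) (2^2 / 2) / sum((xs - mean(xs))^2)
  x_lo <- log2(f[f < 1000] / 1000); x_hi <- log2(f[f > 1000] / 1000)
  rel_low <- stats::var(lows) / (stats::var(lows) + slope_var(x_lo))
  rel_high <- stats::var(highs) / (stats::var(highs) + slope_var(x_hi))
  expect_equal(out$low$r, rel_low, tolerance = 0.03)
  expect_equal(out$high$r, rel_high, tolerance = 0.04)
  expect_gt(out$low$r, out$high$r)   # wider spread, higher reliability
})
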