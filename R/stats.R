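#' Pearson correlation with one-tailed p and Fisher-z confidence interval
#'
#' Product-moment correlation with a t-based p-value in a declared
#' direction (the convention in individual-differences psychoacoustics is
#' one-tailed tests with pre-registered signs) and a two-sided 95%
#' confidence interval from the Fisher r-to-z transform with standard error
#' `1/sqrt(n - 3)`.
#'
#' @param x,y numeric vectors.
#' @param tail `"positive"`, `"negative"` (one-tailed in that direction) or
#'   `"two"`.
#' @param alpha CI level is `1 - alpha` (default .05).
#' @param family_id optional label recording the Holm family the test
#'   belongs to.
#' @return A `correlation_result` list: `r`, `n`, `df`, `t`, `p_raw`,
#'   `ci95`, `tail`, `family_id` (`p_holm` is filled in by family-level
#'   adjustment).
#' @export
pearson_ci <- function(x, y, tail = c("two", "positive", "negative"),
                       alpha = 0.05, family_id = NULL) {
  tail <- match.arg(tail)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  r <- stats::cor(x, y)
  df <- n - 2
  tstat <- r * sqrt(df / (1 - r^2))
  p <- switch(tail,
              two = 2 * stats::pt(-abs(tstat), df),
              positive = stats::pt(tstat, df, lower.tail = FALSE),
              negative = stats::pt(tstat, df))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  crit <- stats::qnorm(1 - alpha / 2)
  ci <- tanh(z + c(-1, 1) * crit * se)
  structure(list(r = r, n = n, df = df, t = tstat, p_raw = p,
                 p_holm = NA_real_, ci95 = ci, tail = tail,
                 family_id = family_id),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d), %s-tailed p = %.4g, 95%% CI [%.3f, %.3f]\n",
              x$r, x$n, if (x$tail == "two") "two" else "one",
              x$p_raw, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Holm step-down familywise adjustment
#'
#' Step-down Holm adjustment with monotonicity enforcement, as implemented
#' in `stats::p.adjust(method = "holm")`. Output is never below the raw p,
#' is monotone in rank, and the procedure is idempotent.
#'
#' @param p_values numeric vector of raw p-values in one declared family.
#' @return adjusted p-values in the input order.
#' @export
holm_adjust <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value family")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "holm")
}

#' Partial correlation by residualization
#'
#' Correlates the OLS residuals of `x` and `y` on a shared covariate set.
#' p and CI use degrees of freedom reduced by the number of covariates:
#' `df = n - 2 - k` for the t-test and `se = 1/sqrt(n - 3 - k)` for the
#' Fisher-z interval. With an empty covariate set this reduces exactly to
#' [pearson_ci()].
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame or matrix of covariates (may be `NULL`).
#' @inheritParams pearson_ci
#' @return A `correlation_result` (with `k` covariates recorded).
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                tail = c("two", "positive", "negative"),
                                alpha = 0.05, family_id = NULL) {
  tail <- match.arg(tail)
  if (is.null(covariates) || NCOL(covariates) == 0)
    return(pearson_ci(x, y, tail = tail, alpha = alpha, family_id = family_id))
  Z <- as.matrix(as.data.frame(covariates))
  ok <- stats::complete.cases(x, y, Z)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(x)
  k <- ncol(Z)
  if (n <= k + 3) stop("need n > number of covariates + 3")
  if (qr(cbind(1, Z))$rank < k + 1)
    stop("rank deficiency: collinear covariates")
  rx <- stats::residuals(stats::lm(x ~ Z))
  ry <- stats::residuals(stats::lm(y ~ Z))
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- switch(tail,
              two = 2 * stats::pt(-abs(tstat), df),
              positive = stats::pt(tstat, df, lower.tail = FALSE),
              negative = stats::pt(tstat, df))
  se <- 1 / sqrt(n - 3 - k)
  crit <- stats::qnorm(1 - alpha / 2)
  ci <- tanh(atanh(r) + c(-1, 1) * crit * se)
  structure(list(r = r, n = n, df = df, t = tstat, p_raw = p,
                 p_holm = NA_real_, ci95 = ci, tail = tail,
                 family_id = family_id, k = k),
            class = "correlation_result")
}

#' Steiger's Z for two dependent overlapping correlations
#'
#' Tests whether `cor(j, k)` differs from `cor(j, h)` when both share the
#' variable `j`, using Dunn and Clark's (1969) Z with Steiger's (1980)
#' modification: the two correlations are pooled (`r_bar = (r_jk + r_jh)/2`)
#' when estimating their covariance.
#'
#' @param r_jk,r_jh the two correlations sharing variable j.
#' @param r_kh the correlation between the two non-shared variables.
#' @param n sample size (> 3).
#' @param tail `"two"` (default), `"positive"` or `"negative"` for the sign
#'   of `r_jk - r_jh`.
#' @return list with `z` and `p`.
#' @export
steiger_z <- function(r_jk, r_jh, r_kh, n,
                      tail = c("two", "positive", "negative")) {
  tail <- match.arg(tail)
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1))
    stop("degenerate correlation (|r| >= 1)")
  if (n <= 3) stop("n must exceed 3")
  rbar <- (r_jk + r_jh) / 2
  cov_term <- (r_kh * (1 - 2 * rbar^2) -
                 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)) / (1 - rbar^2)^2
  z <- sqrt(n - 3) * (atanh(r_jk) - atanh(r_jh)) / sqrt(2 - 2 * cov_term)
  p <- switch(tail,
              two = 2 * stats::pnorm(-abs(z)),
              positive = stats::pnorm(z, lower.tail = FALSE),
              negative = stats::pnorm(z))
  list(z = z, p = p)
}

#' Hierarchical OLS variance decomposition
#'
#' Enters predictors into an ordinary-least-squares model in a declared
#' order and reports the incremental R-squared of each step (which sum
#' exactly to the full-model R-squared), the coefficient p-values from the
#' full model, and the variance inflation factor of each predictor.
#'
#' @param y response vector.
#' @param predictors data.frame of predictors; column order is entry order.
#' @return A `hierarchical_fit` list: `entry_order`, `incremental_R2`,
#'   `full_R2`, `coef_p` (full-model two-sided coefficient p-values),
#'   `vif`, and the full `lm` fit.
#' @export
hierarchical_ols <- function(y, predictors) {
  stopifnot(is.data.frame(predictors), ncol(predictors) >= 1)
  ok <- stats::complete.cases(y, predictors)
  y <- y[ok]; predictors <- predictors[ok, , drop = FALSE]
  n <- length(y)
  p <- ncol(predictors)
  if (n <= p + 2) stop("need n > number of predictors + 2")
  X <- as.matrix(predictors)
  if (qr(cbind(1, X))$rank < p + 1) {
    # identify the first offending predictor
    for (j in seq_len(p)) {
      if (qr(cbind(1, X[, seq_len(j), drop = FALSE]))$rank < j + 1)
        stop("rank deficiency at predictor: ", colnames(X)[j])
    }
  }
  r2 <- numeric(p)
  prev <- 0
  for (j in seq_len(p)) {
    fit_j <- stats::lm(y ~ X[, seq_len(j), drop = FALSE])
    r2j <- summary(fit_j)$r.squared
    r2[j] <- r2j - prev
    prev <- r2j
  }
  dat <- data.frame(y = y, predictors)
  full <- stats::lm(y ~ ., data = dat)
  sm <- summary(full)
  coef_p <- sm$coefficients[-1, 4]
  vifs <- if (p > 1) car::vif(full) else stats::setNames(1, names(predictors))
  structure(list(entry_order = names(predictors),
                 incremental_R2 = stats::setNames(r2, names(predictors)),
                 full_R2 = prev,
                 coef_p = coef_p,
                 vif = vifs,
                 fit = full),
            class = "hierarchical_fit")
}

#' @export
print.hierarchical_fit <- function(x, ...) {
  cat("Hierarchical OLS (entry order):\n")
  for (nm in x$entry_order)
    cat(sprintf("  %-14s incremental R2 = %6.4f  (full-model p = %.4g)\n",
                nm, x$incremental_R2[[nm]], x$coef_p[[paste0(nm)]]))
  cat(sprintf("  full R2 = %.4f\n", x$full_R2))
  invisible(x)
}

#' Bootstrap simulation of test-retest reliability
#'
#' Estimates the ceiling that within-subject run-to-run variability places
#' on between-subject correlations. Per iteration, per subject: draw
#' `runs_per_phase` runs for a test phase and the same number for a retest
#' phase from `Normal(mean_i, sd_i)`; average each phase; correlate the
#' test and retest phase means across subjects. For `kind = "masking-slopes"`
#' the per-condition phase means (all eight pip frequencies) are first
#' converted to low/high masking slopes by linear regression (four
#' regressions per iteration: low/high x test/retest) and the slopes are
#' correlated. Iteration correlations are Fisher-z transformed, averaged,
#' and transformed back.
#'
#' @param scheme data.frame with columns `subject`, `mean`, `sd`; for the
#'   masking kind also `pip_freq` (all eight frequencies per subject).
#' @param kind `"modulation"` (one measure per subject) or
#'   `"masking-slopes"`.
#' @param iterations number of bootstrap iterations (default 1e5; reduce to
#'   1e4 for quick confidence checks).
#' @param runs_per_phase runs drawn per phase (3 for modulation tasks, 2
#'   for masking, following the measurement protocol).
#' @return For `"modulation"`, a list with `r` (the Fisher-z-averaged
#'   test-retest correlation) and `r_iterations`; for `"masking-slopes"`,
#'   the same for both `low` and `high` slopes.
#' @export
bootstrap_test_retest <- function(scheme, kind = c("modulation", "masking-slopes"),
                                  iterations = 1e5,
                                  runs_per_phase = if (kind[1] == "modulation") 3 else 2) {
  kind <- match.arg(kind)
  stopifnot(all(c("subject", "mean", "sd") %in% names(scheme)),
            iterations >= 1)
  if (any(scheme$sd < 0)) stop("within-subject sds must be >= 0")
  fisher_avg <- function(r) {
    r <- r[is.finite(r)]
    if (all(abs(r) >= 1 - 1e-12)) return(sign(mean(r)) * 1)
    tanh(mean(atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))))
  }
  phase_means <- function(mu, sd, k, iter) {
    # mean of k iid normal draws per subject per iteration
    acc <- matrix(0, length(mu), iter)
    for (j in seq_len(k))
      acc <- acc + matrix(stats::rnorm(length(mu) * iter, mu, sd),
                          length(mu), iter)
    acc / k
  }
  col_cor <- function(A, B) {
    A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
    num <- colSums(A * B)
    den <- sqrt(colSums(A^2) * colSums(B^2))
    ifelse(den == 0, NA_real_, num / den)
  }
  chunks <- function(total, size = 10000L) {
    sizes <- rep(size, total %/% size)
    if (total %% size) sizes <- c(sizes, total %% size)
    sizes
  }
  if (kind == "modulation") {
    mu <- scheme$mean; sd <- scheme$sd
    r_it <- unlist(lapply(chunks(iterations), function(it) {
      test <- phase_means(mu, sd, runs_per_phase, it)
      retest <- phase_means(mu, sd, runs_per_phase, it)
      col_cor(test, retest)
    }))
    return(list(r = fisher_avg(r_it), r_iterations = r_it))
  }
  # masking-slopes: regression weights are fixed by the pip frequencies,
  # so each slope is a linear map of the eight phase means
  stopifnot("pip_freq" %in% names(scheme))
  scheme <- scheme[order(scheme$subject, scheme$pip_freq), ]
  freqs <- sort(unique(scheme$pip_freq))
  if (length(freqs) != 8) stop("masking kind needs all 8 pip frequencies")
  subjects <- unique(scheme$subject)
  ns <- length(subjects)
  slope_weights <- function(f) {
    x <- log2(f / 1000)
    (x - mean(x)) / sum((x - mean(x))^2)
  }
  w_low <- slope_weights(freqs[freqs < 1000])
  w_high <- slope_weights(freqs[freqs > 1000])
  low_idx <- which(freqs < 1000); high_idx <- which(freqs > 1000)
  mu <- matrix(scheme$mean, nrow = 8)       # 8 x ns, freq-major per subject
  sd <- matrix(scheme$sd, nrow = 8)
  muv <- as.vector(mu); sdv <- as.vector(sd)
  slopes_one_phase <- function(it) {
    acc <- matrix(0, 8, ns * it)
    for (j in seq_len(runs_per_phase))
      acc <- acc + matrix(stats::rnorm(8 * ns * it, muv, sdv), 8, ns * it)
    pm <- acc / runs_per_phase
    list(low = matrix(crossprod(w_low, pm[low_idx, , drop = FALSE]), ns, it),
         high = matrix(crossprod(w_high, pm[high_idx, , drop = FALSE]), ns, it))
  }
  rs <- lapply(chunks(iterations, 2000L), function(it) {
    test <- slopes_one_phase(it)
    retest <- slopes_one_phase(it)
    list(low = col_cor(test$low, retest$low),
         high = col_cor(test$high, retest$high))
  })
  r_low <- unlist(lapply(rs, `[[`, "low"))
  r_high <- unlist(lapply(rs, `[[`, "high"))
  list(low = list(r = fisher_avg(r_low), r_iterations = r_low),
       high = list(r = fisher_avg(r_high), r_iterations = r_high))
}
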