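test_that("deterministic limits: zero slope noise gives perfect HL-slope correlation", {
  p <- cohort_params(slope_low = list(mean = 49.4, coef = -1.3, r = -1),
                     slope_high = list(mean = -23.3, coef = 0.62, r = 1))
  coh <- generate_cohort(n = 20, params = p, seed = 1, measure = "latent")
  expect_equal(stats::cor(coh$abs_thresh_1k, coh$low_slope_true), -1,
               tolerance = 1e-12)
  expect_equal(stats::cor(coh$abs_thresh_1k, coh$high_slope_true), 1,
               tolerance = 1e-12)
})

test_that("noiseless masking patterns recover the true slopes exactly", {
  subj <- list(low_slope = 40, high_slope = -25, masker_level = 65,
               pip_abs = 10)
  pat <- simulate_masking_pattern(subj, run_sd = 0)
  sl <- fit_masking_slopes(rowMeans(pat$final))
  expect_equal(sl$low_slope, 40, tolerance = 1e-9)
  expect_equal(sl$high_slope, -25, tolerance = 1e-9)

  # triangular shape: inner pip frequencies more masked than outer ones
  f <- pip_frequencies()
  expect_true(all(pat$true_pattern[f %in% c(980, 1020)] >
                    pat$true_pattern[f %in% c(800, 1200)]))
})

test_that("slope recovery from noisy patterns is nearly unbiased", {
  set.seed(21)
  n <- 1000
  est <- replicate(n, {
    pat <- simulate_masking_pattern(
      list(low_slope = 50, high_slope = -20, masker_level = 65,
           pip_abs = 5), run_sd = 2)
    sl <- fit_masking_slopes(rowMeans(pat$final))
    c(sl$low_slope, sl$high_slope)
  })
  expect_lt(abs(mean(est[1, ]) - 50), 2)
  expect_lt(abs(mean(est[2, ]) + 20), 2)
})

test_that("re-run rule trims the upper tail of the across-run SD distribution", {
  subj <- list(low_slope = 50, high_slope = -20, masker_level = 65,
               pip_abs = 5)
  collect_sds <- function(rerun_sd, seed) {
    set.seed(seed)
    unlist(replicate(400, {
      pat <- simulate_masking_pattern(subj, run_sd = 3, rerun_sd = rerun_sd)
      apply(pat$final, 1, stats::sd)
    }, simplify = FALSE))
  }
  with_rule <- collect_sds(4, 31)
  without <- collect_sds(Inf, 31)
  expect_lt(stats::quantile(with_rule, 0.97), stats::quantile(without, 0.97))
  expect_lt(mean(with_rule >= 6), mean(without >= 6))
})

test_that("default cohorts reproduce the designed correlational structure", {
  coh <- generate_cohort(n = 55, seed = 101)
  expect_equal(nrow(coh), 55)
  expect_true(all(coh$abs_thresh_1k < 70))
  expect_true(all(coh$age >= 19 & coh$age <= 79))
  # shared-code ordering: slow FM attaches to fast FM more strongly than to
  # slow AM
  expect_gt(stats::cor(coh$slow_fm, coh$fast_fm),
            stats::cor(coh$slow_fm, coh$slow_am))
  # hearing loss correlates negatively with the low slope, positively with
  # the high slope
  expect_lt(stats::cor(coh$abs_thresh_1k, coh$low_slope), -0.4)
  expect_gt(stats::cor(coh$abs_thresh_1k, coh$high_slope), 0.4)
  # generation is seed-reproducible
  coh2 <- generate_cohort(n = 55, seed = 101)
  expect_identical(as.data.frame(coh), as.data.frame(coh2))
})

test_that("outlier injection exercises the 3-SD exclusion rule", {
  coh <- generate_cohort(n = 30, params = cohort_params(inject_outlier = TRUE),
                         seed = 5, measure = "latent")
  z <- abs(coh$slow_fm - mean(coh$slow_fm)) / stats::sd(coh$slow_fm)
  expect_gt(max(z), 3)
})

test_that("Experiment-2 generator reproduces its cell-mean template in the zero-noise limit", {
  p0 <- exp2_params(disc_subject_sd = 0, disc_run_sd = 0,
                    det_subject_sd = 0)
  e2 <- generate_exp2_cohort(n = 6, params = p0, seed = 3)
  d <- e2$discrimination
  # recompute the template independently from the parameter lists
  h <- c(slow = -1, fast = 1)
  mu <- p0$disc_base + p0$disc_center[as.character(d$center)] +
    p0$disc_rate[d$rate] +
    p0$disc_interaction_g[as.character(d$center)] * h[d$rate] +
    p0$disc_sep[d$separation] +
    p0$disc_sep_center[as.character(d$center)] *
      ifelse(d$separation == "wide", -1, 1)
  expect_equal(d$threshold, unname(mu), tolerance = 1e-12)
  # the built-in slow-rate advantage: slow < fast at 500/1500, absent at 7000
  cell <- tapply(d$threshold, list(d$center, d$rate), mean)
  expect_lt(cell["500", "slow"], cell["500", "fast"])
  expect_lt(cell["1500", "slow"], cell["1500", "fast"])
  expect_equal(cell["7000", "slow"], cell["7000", "fast"], tolerance = 1e-12)
})

test_that("source-data export round-trips and matches the documented shapes", {
  coh <- generate_cohort(n = 12, seed = 7, measure = "latent")
  e2 <- generate_exp2_cohort(n = 20, seed = 7)
  outdir <- tempfile()
  paths <- export_source_data(coh, outdir, exp2 = e2)
  expect_length(paths, 5)

  f2 <- read_source_data(file.path(outdir, "figure2_source_data.csv"), 2)
  expect_equal(f2$thresh_1k, coh$abs_thresh_1k)
  expect_equal(f2$low_slope, coh$low_slope)
  f3 <- read_source_data(file.path(outdir, "figure3_source_data.csv"), 3)
  expect_equal(f3$slow_fm, coh$slow_fm)
  expect_equal(f3$fast_am, coh$fast_am)
  f4 <- read_source_data(file.path(outdir, "figure4_source_data.csv"), 4)
  expect_equal(f4$high_slope, coh$high_slope)

  # figure-6 export: 20 subjects x (12 discrimination + 24 detection)
  fig6 <- utils::read.csv(file.path(outdir, "figure6_source_data.csv"))
  expect_equal(dim(fig6), c(20, 1 + 12 + 24))
  f6 <- read_source_data(file.path(outdir, "figure6_source_data.csv"), 6)
  expect_equal(nrow(f6$discrimination), 20 * 12)
  expect_equal(nrow(f6$detection), 20 * 24)
  # values survive the round trip
  d0 <- e2$discrimination[order(e2$discrimination$subject,
                                e2$discrimination$center,
                                e2$discrimination$rate,
                                e2$discrimination$separation), ]
  d1 <- f6$discrimination[order(f6$discrimination$subject,
                                f6$discrimination$center,
                                f6$discrimination$rate,
                                f6$discrimination$separation), ]
  expect_equal(d1$threshold, d0$threshold, tolerance = 1e-9)
})
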