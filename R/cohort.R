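#' Default generator parameters for the synthetic listener cohort
#'
#' The defaults emulate the study conditions of the individual-differences
#' experiment: 1-kHz absolute thresholds spread evenly over 0-70 dB SPL,
#' masking-function slopes linear in hearing loss with population
#' correlations of -0.7 (low slope) and +0.7 (high slope) and means of
#' 49.4 and -23.3 dB/octave, FM thresholds generated from the
#' excitation-pattern model with a per-rate level-difference criterion, AM
#' thresholds driven by a shared efficiency (internal noise) latent, and a
#' mild age dependence of both. See the methods vignette for the rationale
#' behind every number.
#'
#' @param ... named overrides of any default component.
#' @return list of generator parameters.
#' @export
cohort_params <- function(...) {
  p <- list(
    hl_range = c(0, 70),            # dB SPL, uniform absolute thresholds
    age = list(intercept = 45, slope = 0.45, sd = 8, range = c(19, 79)),
    slope_low = list(mean = 49.4, coef = -1.3, r = -0.7),
    slope_high = list(mean = -23.3, coef = 0.62, r = 0.7),
    slope_noise_taper = 0.7,        # slope dispersion shrinks with HL (funnel)
    criterion_dL = c(slow = 0.5, fast = 1.0),  # dB, place-model criterion
    fm_ceiling_pct = 30,            # 2*delta-f % cap when place cue absent
    efficiency_sd = 2,              # dB on the 10log/20log threshold scale
    fm_eff_weight = c(slow = 0.3, fast = 0.8),
    fm_age_coef = 0.03,             # dB per year re: age 60
    fm_resid_sd = 0.8,
    am_base = c(slow = -26.5, fast = -25.5),  # 20log10(m) dB
    am_age_coef = 0.02,
    am_resid_sd = 1.5,
    observer_sigma = 3,             # psychometric spread, dB-equivalent
    lapse = 0.01,
    n_runs = 3, rerun_sd = 4,       # re-run rule: 3 extra runs if SD >= 4
    masker_offset = 0,              # pattern peak at the masker level
    masking_run_sd = 2,             # dB per masked-threshold run
    pip_abs_offset = 8,             # 20-ms pip threshold re: 500-ms tone
    inject_outlier = FALSE          # one > 3 SD FM outlier, if wanted
  )
  utils::modifyList(p, list(...))
}

slope_noise_sd <- function(coef, r, hl_range) {
  sd_hl <- diff(hl_range) / sqrt(12)
  if (abs(r) >= 1) return(0)
  abs(coef) * sd_hl * sqrt(1 / r^2 - 1)
}

# measure one threshold with n staircase runs (+ re-run rule); returns
# mean, sd over the analyzed runs, and the per-run values
measure_runs <- function(preset_name, mu, sigma, lapse, n_runs, rerun_sd,
                         to_stat, start_value = NULL) {
  cfg <- staircase_preset(preset_name, start_value = start_value)
  obs <- sim_observer(mu = mu, sigma = sigma, lapse = lapse,
                      log_domain = (cfg$step_mode == "factor"))
  one <- function() {
    res <- run_staircase(cfg, obs)
    if (is.na(res$threshold)) return(NA_real_)
    to_stat(res$threshold)
  }
  runs <- replicate(n_runs, one())
  if (stats::sd(runs, na.rm = TRUE) >= rerun_sd || anyNA(runs))
    runs <- replicate(n_runs, one())
  list(mean = mean(runs, na.rm = TRUE), sd = stats::sd(runs, na.rm = TRUE),
       runs = runs)
}

#' Generate a synthetic Experiment-1-style cohort
#'
#' Draws latent subject parameters (hearing loss, age, true excitation-
#' pattern slopes, efficiency), derives true FM thresholds from the place
#' model and AM thresholds from efficiency, then re-measures all four
#' modulation thresholds through simulated adaptive staircases (three runs
#' each, with the "SD >= 4 -> re-run" data-quality rule) and the forward-
#' masking pattern through noisy runs, from which the masking slopes are
#' re-fitted by regression. The returned table therefore carries both the
#' latent truth and the measured quantities that the statistics chain sees.
#'
#' @param n number of subjects (>= 10; default 55).
#' @param params a [cohort_params()] list.
#' @param seed integer seed (all generation is seed-reproducible).
#' @param measure `"staircase"` (default: thresholds measured through
#'   simulated adaptive tracks) or `"latent"` (no measurement noise beyond
#'   the generative model; fast, used for calibration checks).
#' @return A `cohort_table` data.frame, one row per subject, with latent
#'   columns (`*_true`, `efficiency`), measured thresholds in the analysis
#'   units (`slow_fm`/`fast_fm` in 10log10(2*delta-f %); `slow_am`/`fast_am`
#'   in 20log10(m) dB), per-task run SDs, fitted `low_slope`/`high_slope`,
#'   and the masked-threshold runs as attributes.
#' @export
generate_cohort <- function(n = 55, params = cohort_params(), seed = 1,
                            measure = c("staircase", "latent")) {
  measure <- match.arg(measure)
  if (n < 10) stop("n must be >= 10")
  set.seed(seed)
  p <- params
  hl <- stats::runif(n, p$hl_range[1], p$hl_range[2])
  age <- p$age$intercept + p$age$slope * hl + stats::rnorm(n, 0, p$age$sd)
  age <- pmin(pmax(age, p$age$range[1]), p$age$range[2])
  mean_hl <- mean(p$hl_range)
  s_lo <- p$slope_low; s_hi <- p$slope_high
  sd_lo <- slope_noise_sd(s_lo$coef, s_lo$r, p$hl_range)
  sd_hi <- slope_noise_sd(s_hi$coef, s_hi$r, p$hl_range)
  if (abs(s_lo$r) > 1 || abs(s_hi$r) > 1)
    stop("infeasible correlation target (|r| > 1)")
  # heteroscedastic slope noise: dispersion tapers linearly with hearing
  # loss (broader filters vary less), rescaled so the marginal noise
  # variance -- and hence the configured population correlation -- is kept
  tp <- p$slope_noise_taper
  u <- (hl - p$hl_range[1]) / diff(p$hl_range)
  taper <- (1 - tp * u) / sqrt(1 - tp + tp^2 / 3)
  low_true <- (s_lo$mean - s_lo$coef * mean_hl) + s_lo$coef * hl +
    stats::rnorm(n, 0, sd_lo) * taper
  high_true <- (s_hi$mean - s_hi$coef * mean_hl) + s_hi$coef * hl +
    stats::rnorm(n, 0, sd_hi) * taper
  eff <- stats::rnorm(n, 0, p$efficiency_sd)
  true_fm <- function(rate) {
    pp <- vapply(seq_len(n), function(i) {
      v <- predict_fm_threshold(filter_slopes(low_true[i], high_true[i]),
                                criterion_dL = p$criterion_dL[[rate]])
      if (is.na(v) || v > p$fm_ceiling_pct) p$fm_ceiling_pct else v
    }, numeric(1))
    10 * log10(pp) + p$fm_eff_weight[[rate]] * eff +
      p$fm_age_coef * (age - 60) + stats::rnorm(n, 0, p$fm_resid_sd)
  }
  true_am <- function(rate) {
    pmin(p$am_base[[rate]] + eff + p$am_age_coef * (age - 60) +
           stats::rnorm(n, 0, p$am_resid_sd), -0.5)
  }
  truth <- list(slow_fm = true_fm("slow"), fast_fm = true_fm("fast"),
                slow_am = true_am("slow"), fast_am = true_am("fast"))
  if (isTRUE(p$inject_outlier)) {
    truth$slow_fm[1] <- truth$slow_fm[1] + 6 * stats::sd(truth$slow_fm)
    truth$fast_fm[1] <- truth$fast_fm[1] + 6 * stats::sd(truth$fast_fm)
  }
  meas <- list(); run_sd <- list()
  for (task in names(truth)) {
    is_fm <- grepl("fm$", task)
    if (measure == "latent") {
      meas[[task]] <- truth[[task]]
      run_sd[[task]] <- rep(0, n)
    } else {
      out <- lapply(seq_len(n), function(i) {
        measure_runs(if (is_fm) "fm_1kHz" else "am_1kHz",
                     mu = truth[[task]][i], sigma = p$observer_sigma,
                     lapse = p$lapse, n_runs = p$n_runs,
                     rerun_sd = p$rerun_sd,
                     to_stat = if (is_fm) function(th) 10 * log10(th)
                               else identity)
      })
      meas[[task]] <- vapply(out, `[[`, numeric(1), "mean")
      run_sd[[task]] <- vapply(out, `[[`, numeric(1), "sd")
    }
  }
  # forward-masking patterns and fitted slopes
  masker_level <- pmax(65, hl + 20)
  patterns <- lapply(seq_len(n), function(i) {
    simulate_masking_pattern(
      list(low_slope = low_true[i], high_slope = high_true[i],
           masker_level = masker_level[i],
           pip_abs = hl[i] + p$pip_abs_offset),
      run_sd = if (measure == "latent") 0 else p$masking_run_sd,
      masker_offset = p$masker_offset, rerun_sd = p$rerun_sd)
  })
  fitted <- lapply(patterns, function(pt) fit_masking_slopes(rowMeans(pt$final)))
  tab <- data.frame(
    subject = sprintf("S%02d", seq_len(n)),
    age = age,
    abs_thresh_1k = hl,
    low_slope_true = low_true, high_slope_true = high_true,
    efficiency = eff,
    low_slope = vapply(fitted, `[[`, numeric(1), "low_slope"),
    high_slope = vapply(fitted, `[[`, numeric(1), "high_slope"),
    slow_fm = meas$slow_fm, fast_fm = meas$fast_fm,
    slow_am = meas$slow_am, fast_am = meas$fast_am,
    slow_fm_sd = run_sd$slow_fm, fast_fm_sd = run_sd$fast_fm,
    slow_am_sd = run_sd$slow_am, fast_am_sd = run_sd$fast_am,
    masker_level = masker_level,
    stringsAsFactors = FALSE)
  attr(tab, "masking_patterns") <- patterns
  attr(tab, "params") <- p
  attr(tab, "seed") <- seed
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Simulate a forward-masking pattern for one subject
#'
#' Masked thresholds at the eight pip frequencies follow the triangular
#' excitation pattern anchored at the masker: the pattern peak sits
#' `masker_offset` dB below the masker level at 1 kHz and falls away with
#' the subject's true low/high slopes; each run adds Gaussian noise of SD
#' `run_sd` and is floored at the pip absolute threshold. Two runs are
#' produced per frequency; if their SD reaches `rerun_sd`, two replacement
#' runs are drawn (the data-quality rule) and only the final two are
#' analyzed.
#'
#' @param subj list with `low_slope`, `high_slope`, `masker_level`,
#'   `pip_abs` (pip absolute threshold, dB SPL).
#' @param run_sd per-run threshold noise, dB.
#' @param masker_offset dB between masker level and pattern peak.
#' @param rerun_sd re-run trigger (SD across the two runs), dB.
#' @return list with `final` (8 x 2 matrix of analyzed runs, rows ordered
#'   as [pip_frequencies()]), `all_runs`, and `true_pattern`.
#' @export
simulate_masking_pattern <- function(subj, run_sd = 2, masker_offset = 0,
                                     rerun_sd = 4) {
  f <- pip_frequencies()
  peak <- subj$masker_level - masker_offset
  side_slope <- ifelse(f < 1000, subj$low_slope, subj$high_slope)
  pattern <- pmax(peak + side_slope * log2(f / 1000), subj$pip_abs)
  draw2 <- function() {
    matrix(pmax(pattern + stats::rnorm(16, 0, run_sd), subj$pip_abs),
           nrow = 8)
  }
  runs <- draw2()
  all_runs <- runs
  redo <- apply(runs, 1, stats::sd) >= rerun_sd
  if (any(redo)) {
    runs2 <- draw2()
    runs[redo, ] <- runs2[redo, ]
    all_runs <- cbind(all_runs, runs2)
  }
  list(final = runs, all_runs = all_runs, true_pattern = pattern)
}

#' Bootstrap scheme from a measured cohort
#'
#' Extracts the per-subject (mean, sd) table that
#' [bootstrap_test_retest()] consumes, for one modulation task or for the
#' masked thresholds.
#'
#' @param cohort a [generate_cohort()] table.
#' @param task one of `"slow_fm"`, `"fast_fm"`, `"slow_am"`, `"fast_am"`,
#'   or `"masking"`.
#' @return data.frame with `subject`, (`pip_freq`,) `mean`, `sd`.
#' @export
bootstrap_scheme <- function(cohort, task) {
  if (task == "masking") {
    pats <- attr(cohort, "masking_patterns")
    do.call(rbind, lapply(seq_along(pats), function(i) {
      fin <- pats[[i]]$final
      data.frame(subject = cohort$subject[i], pip_freq = pip_frequencies(),
                 mean = rowMeans(fin), sd = apply(fin, 1, stats::sd))
    }))
  } else {
    data.frame(subject = cohort$subject,
               mean = cohort[[task]], sd = cohort[[paste0(task, "_sd")]])
  }
}
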