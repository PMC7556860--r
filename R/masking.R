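#' The eight standard tone-pip frequencies
#'
#' Four below and four above the 1-kHz masker.
#' @return numeric vector of Hz.
#' @export
pip_frequencies <- function() c(800, 860, 920, 980, 1020, 1080, 1140, 1200)

#' Estimate masking-function slopes from a forward-masking pattern
#'
#' Fits ordinary least squares of masked threshold (dB SPL) on
#' `log2(f/1000)` separately over the four pip frequencies below and the
#' four above the masker. Units are dB/octave; the log2 abscissa is the only
#' convention consistent with dB/octave. The low slope is positive when
#' thresholds rise toward the masker from below; the high slope is
#' typically negative.
#'
#' @param masked_thresh numeric length-8 vector of masked thresholds in
#'   dB SPL, ordered as [pip_frequencies()]; or a named vector keyed by
#'   frequency.
#' @param pip_freqs pip frequencies in Hz (default the standard eight).
#' @return A [filter_slopes()].
#' @export
fit_masking_slopes <- function(masked_thresh, pip_freqs = pip_frequencies()) {
  if (length(masked_thresh) != length(pip_freqs))
    stop("need one threshold per pip frequency")
  if (!all(is.finite(masked_thresh))) stop("all thresholds must be finite")
  below <- pip_freqs < 1000
  above <- pip_freqs > 1000
  if (sum(below) < 4 || sum(above) < 4)
    stop("need at least 4 pip frequencies on each side of the masker")
  x <- log2(pip_freqs / 1000)
  low <- stats::coef(stats::lm(masked_thresh[below] ~ x[below]))[2]
  high <- stats::coef(stats::lm(masked_thresh[above] ~ x[above]))[2]
  filter_slopes(unname(low), unname(high))
}

#' Sensitivity of the slope-based analyses to "opposite"-sign slopes
#'
#' Re-runs the FM-slope correlation family under an imputation policy for
#' subjects whose fitted slopes have the atypical sign (negative low slope
#' or positive high slope): either impute those slope values with 0 or drop
#' those subjects, and report the change in r, one-tailed p, and the
#' significance flag for each correlation.
#'
#' @param cohort a cohort table from [generate_cohort()] (or any data.frame
#'   with `low_slope`, `high_slope`, `slow_fm`, `fast_fm` columns).
#' @param policy `"impute-zero"` or `"drop"`.
#' @param alpha significance level for the flags (default .05, on Holm-
#'   adjusted p within the 4-correlation family).
#' @return A data.frame with baseline and policy r/p per correlation, the
#'   deltas, significance flags, the number of affected subjects and the
#'   policy n.
#' @export
slope_robustness <- function(cohort, policy = c("impute-zero", "drop"),
                             alpha = 0.05) {
  policy <- match.arg(policy)
  stopifnot(all(c("low_slope", "high_slope", "slow_fm", "fast_fm")
                %in% names(cohort)))
  opp <- cohort$low_slope < 0 | cohort$high_slope > 0
  mod <- cohort
  if (policy == "impute-zero") {
    mod$low_slope[mod$low_slope < 0] <- 0
    mod$high_slope[mod$high_slope > 0] <- 0
  } else {
    mod <- mod[!opp, , drop = FALSE]
  }
  pairs <- data.frame(slope = rep(c("low_slope", "high_slope"), each = 2),
                      fm = rep(c("slow_fm", "fast_fm"), 2),
                      stringsAsFactors = FALSE)
  tail_for <- function(slope) if (slope == "low_slope") "negative" else "positive"
  run <- function(d) {
    res <- mapply(function(s, f) {
      ct <- pearson_ci(d[[s]], d[[f]], tail = tail_for(s))
      c(r = ct$r, p = ct$p_raw)
    }, pairs$slope, pairs$fm)
    data.frame(r = res["r", ], p = res["p", ])
  }
  base <- run(cohort)
  alt <- run(mod)
  base_holm <- holm_adjust(base$p)
  alt_holm <- holm_adjust(alt$p)
  data.frame(slope = pairs$slope, fm = pairs$fm,
             r_baseline = base$r, r_policy = alt$r,
             delta_r = alt$r - base$r,
             p_baseline = base$p, p_policy = alt$p,
             delta_p = alt$p - base$p,
             sig_baseline = base_holm < alpha,
             sig_policy = alt_holm < alpha,
             sig_changed = (base_holm < alpha) != (alt_holm < alpha),
             n_affected = sum(opp), n_policy = nrow(mod),
             policy = policy, row.names = NULL)
}
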