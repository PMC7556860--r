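#' Masking-function filter slopes
#'
#' The behavioral estimate of excitation-pattern (place-coding) fidelity:
#' the low-frequency and high-frequency slopes of the forward-masking
#' pattern, in dB/octave. Sign convention: `low_slope` is the fitted
#' regression coefficient of masked threshold on log2 frequency below the
#' masker, positive when thresholds rise toward the masker; `high_slope` is
#' the coefficient above the masker, typically negative. "Opposite"-sign
#' slopes (negative low / positive high) occur under measurement noise and
#' are kept as fitted.
#'
#' @param low_slope low-side slope, dB/octave.
#' @param high_slope high-side slope, dB/octave.
#' @return A `filter_slopes` list.
#' @export
filter_slopes <- function(low_slope, high_slope) {
  stopifnot(is.finite(low_slope), is.finite(high_slope))
  structure(list(low_slope = low_slope, high_slope = high_slope),
            class = "filter_slopes")
}

# octave width swept by a peak-to-peak excursion of pp % of the carrier
excursion_octaves <- function(pp_excursion_pct) {
  df <- pp_excursion_pct / 200        # single-sided fractional excursion
  log2((1 + df) / (1 - df))
}

#' FM-induced level fluctuation on a triangular excitation pattern
#'
#' Under a place code, a frequency excursion sweeping `delta-oct` octaves
#' across an excitation pattern that is linear in dB vs log2-frequency
#' produces a peak-to-peak level change of `|slope| * delta-oct` dB on each
#' side. Steeper slopes give larger level cues (better FM coding); the side
#' with the larger fluctuation dominates detection.
#'
#' @param slopes a [filter_slopes()].
#' @param pp_excursion_pct peak-to-peak excursion 2*delta-f as % of the
#'   carrier; must be in (0, 200).
#' @return A list with `delta_L_low`, `delta_L_high` (dB, both >= 0) and
#'   `dominant_side` (`"low"` or `"high"`).
#' @export
fm_induced_level_change <- function(slopes, pp_excursion_pct) {
  stopifnot(inherits(slopes, "filter_slopes"))
  if (pp_excursion_pct <= 0) stop("excursion must be > 0")
  if (pp_excursion_pct >= 200) stop("excursion must be < 200%")
  doct <- excursion_octaves(pp_excursion_pct)
  dl_low <- abs(slopes$low_slope) * doct
  dl_high <- abs(slopes$high_slope) * doct
  list(delta_L_low = dl_low, delta_L_high = dl_high,
       dominant_side = if (dl_low >= dl_high) "low" else "high")
}

#' Place-model response to AM
#'
#' On the place model the AM depth at the output of any linear (in dB)
#' excitation pattern equals the input depth: filter slopes scale the
#' mean level, not the modulation depth. This invariance is what dissociates
#' AM from FM in the model.
#'
#' @param slopes a [filter_slopes()] (unused except for validation).
#' @param depth_db AM depth `20*log10(m)` in dB; `m` must be in (0, 1].
#' @return `depth_db`, unchanged.
#' @export
am_place_response <- function(slopes, depth_db) {
  stopifnot(inherits(slopes, "filter_slopes"))
  m <- 10^(depth_db / 20)
  if (m <= 0 || m > 1 + 1e-12) stop("AM depth must give m in (0, 1]")
  depth_db
}

#' Predict the FM detection threshold from filter slopes
#'
#' Inverts [fm_induced_level_change()]: the smallest peak-to-peak excursion
#' (in % of the carrier) whose dominant-side level fluctuation reaches
#' `criterion_dL * efficiency` dB. With the dominant-side rule the inverse
#' is closed-form:
#' `delta-oct = criterion_dL * efficiency / max(|low|, |high|)` and
#' `2*delta-f(%) = 200 * (2^delta-oct - 1) / (2^delta-oct + 1)`.
#'
#' @param slopes a [filter_slopes()].
#' @param criterion_dL level-difference detection criterion, dB (the free
#'   calibration parameter of the model; the source text states none).
#' @param efficiency internal-noise multiplier, >= 1 for poorer-than-ideal
#'   observers; scales the threshold proportionally in the linear regime.
#' @param rule `"dominant"` (max of the two sides, default) or
#'   `"quadrature"` (root-sum-of-squares combination of both sides).
#' @return predicted threshold 2*delta-f in %, or `NA` (the "no place cue"
#'   sentinel) when both slopes are zero.
#' @export
predict_fm_threshold <- function(slopes, criterion_dL, efficiency = 1,
                                 rule = c("dominant", "quadrature")) {
  stopifnot(inherits(slopes, "filter_slopes"), criterion_dL > 0,
            efficiency > 0)
  rule <- match.arg(rule)
  s_eff <- switch(rule,
                  dominant = max(abs(slopes$low_slope), abs(slopes$high_slope)),
                  quadrature = sqrt(slopes$low_slope^2 + slopes$high_slope^2))
  if (s_eff == 0) return(NA_real_)   # no place cue
  doct <- criterion_dL * efficiency / s_eff
  r <- 2^doct
  200 * (r - 1) / (r + 1)
}
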