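#' Sampled audio waveform
#'
#' Container for every synthesized stimulus. Samples are in normalized
#' full-scale units; the nominal presentation level is carried as metadata
#' under the package's calibration convention (see Details).
#'
#' @details The package uses a fixed calibration constant: a full-scale
#' sinusoid (peak amplitude 1) corresponds to a nominal 100 dB SPL. All
#' `level_spl` fields are nominal levels under this convention; absolute
#' hardware calibration is out of scope. The scale factor for a tone at
#' `L` dB SPL is therefore `10^((L - 100)/20)`.
#'
#' @param samples numeric vector, or a two-column matrix for binaural
#'   stimuli (column 1 = target ear, column 2 = contralateral).
#' @param fs sampling rate in Hz.
#' @param level_spl nominal presentation level in dB SPL.
#' @param channel_tag one of `"target-ear"`, `"contralateral"`, `"diotic"`,
#'   `"binaural"`.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, fs, level_spl = NA_real_,
                     channel_tag = c("target-ear", "contralateral",
                                     "diotic", "binaural")) {
  channel_tag <- match.arg(channel_tag)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!all(is.finite(samples))) stop("all samples must be finite")
  if (max(abs(samples)) > 1 + 1e-9) stop("|samples| must be <= 1 (full scale)")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  structure(list(samples = samples, fs = fs, level_spl = level_spl,
                 channel_tag = channel_tag),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  n <- if (is.matrix(x$samples)) nrow(x$samples) else length(x$samples)
  cat(sprintf("<waveform> %d samples @ %g Hz (%.1f ms), %s, level %s dB SPL\n",
              n, x$fs, 1000 * n / x$fs, x$channel_tag,
              format(x$level_spl)))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param wave a [waveform()].
#' @return duration in seconds.
#' @export
wave_duration <- function(wave) {
  n <- if (is.matrix(wave$samples)) nrow(wave$samples) else length(wave$samples)
  n / wave$fs
}

# dB SPL -> peak amplitude in full-scale units (0 dBFS sine ~ 100 dB SPL)
spl_to_amp <- function(level_spl) 10^((level_spl - 100) / 20)

#' Apply raised-cosine onset/offset ramps
#'
#' Multiplies the first and last `ramp_ms` of a waveform by raised-cosine
#' (Hann-shaped) ramps; the interior is untouched and the total duration is
#' unchanged. `ramp_ms = 0` is the identity.
#'
#' @param wave a [waveform()].
#' @param ramp_ms ramp duration in milliseconds. Must not exceed half the
#'   stimulus duration.
#' @return The ramped [waveform()].
#' @export
apply_raised_cosine_ramp <- function(wave, ramp_ms) {
  stopifnot(inherits(wave, "waveform"), is.numeric(ramp_ms), ramp_ms >= 0)
  if (ramp_ms == 0) return(wave)
  x <- wave$samples
  n <- if (is.matrix(x)) nrow(x) else length(x)
  nr <- round(ramp_ms / 1000 * wave$fs)
  if (2 * nr > n) stop("ramp longer than half the stimulus duration")
  # ramp sample i (0-based) gets gain 0.5*(1 - cos(pi*i/nr)); the midpoint
  # of the ramp (t = ramp_ms/2 into the stimulus) has gain exactly 0.5
  g <- 0.5 * (1 - cos(pi * (0:(nr - 1)) / nr))
  env <- rep(1, n)
  env[1:nr] <- g
  env[n:(n - nr + 1)] <- g
  wave$samples <- if (is.matrix(x)) x * env else x * env
  wave
}

# -- small DSP helpers (internal) --------------------------------------------

# analytic signal via FFT (Marple 1999 construction)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert envelope of a waveform
#'
#' Magnitude of the analytic signal, used for checking AM depths and the
#' envelope flatness of FM tones.
#'
#' @param x numeric vector or [waveform()].
#' @return numeric vector of envelope values.
#' @export
hilbert_envelope <- function(x) {
  if (inherits(x, "waveform")) x <- x$samples
  Mod(analytic_signal(as.numeric(x)))
}

# phase unwrap (jumps > pi folded back)
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

#' Instantaneous frequency by the phase-derivative method
#'
#' Demodulates a (possibly frequency-modulated) tone: the derivative of the
#' unwrapped analytic phase divided by 2*pi. Returns one value per sample
#' (forward difference, last value repeated).
#'
#' @param x numeric vector or [waveform()].
#' @param fs sampling rate in Hz (taken from the waveform if omitted).
#' @return numeric vector of instantaneous frequency in Hz.
#' @export
instantaneous_frequency <- function(x, fs = NULL) {
  if (inherits(x, "waveform")) { fs <- x$fs; x <- x$samples }
  stopifnot(!is.null(fs))
  ph <- unwrap_phase(Arg(analytic_signal(as.numeric(x))))
  f <- diff(ph) * fs / (2 * pi)
  c(f, f[length(f)])
}

# Hilbert envelope of the band around a carrier, via Butterworth band-pass
band_envelope <- function(x, fs, f_center, half_width_oct = 0.25, order = 4) {
  lo <- f_center * 2^(-half_width_oct)
  hi <- f_center * 2^(half_width_oct)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  hilbert_envelope(y)
}
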