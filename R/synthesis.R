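#' Modulation specification for a single-carrier stimulus
#'
#' @param kind `"FM"` or `"AM"`.
#' @param f_m modulation rate in Hz.
#' @param depth for FM, the peak-to-peak frequency excursion 2*delta-f as a
#'   percentage of the carrier; for AM, the depth in dB, `20*log10(m)` with
#'   modulation index `m` in (0, 1].
#' @param onset_rule `"increasing"`, `"decreasing"` or `"random"`. Targets
#'   start with either a rising or falling modulator with 50% probability
#'   when `"random"`; the two possibilities are starting phases 0 and pi.
#' @return A `modulation_spec` list.
#' @export
modulation_spec <- function(kind = c("FM", "AM"), f_m, depth,
                            onset_rule = c("random", "increasing", "decreasing")) {
  kind <- match.arg(kind)
  onset_rule <- match.arg(onset_rule)
  if (kind == "FM" && depth <= 0) stop("FM depth (2*delta-f %) must be > 0")
  if (kind == "AM") {
    m <- 10^(depth / 20)
    if (m <= 0 || m > 1 + 1e-12) stop("AM depth must give m in (0, 1]")
  }
  structure(list(kind = kind, f_m = f_m, depth = depth,
                 onset_rule = onset_rule), class = "modulation_spec")
}

resolve_onset_phase <- function(onset_rule) {
  switch(onset_rule,
         increasing = 0,
         decreasing = pi,
         random = if (stats::runif(1) < 0.5) 0 else pi)
}

#' Synthesize a sinusoidally frequency-modulated tone
#'
#' Instantaneous frequency is
#' `f_c * (1 + (delta_f/100) * sin(2*pi*f_m*t + phi0))` where `delta_f`
#' is half the peak-to-peak excursion (`spec$depth / 2`, in percent of the
#' carrier) and `phi0` follows the onset rule. The envelope is flat before
#' ramping; ramps are applied here.
#'
#' @param f_c carrier frequency, Hz.
#' @param spec a [modulation_spec()] with `kind = "FM"`.
#' @param dur duration in seconds.
#' @param level_spl nominal level, dB SPL.
#' @param fs sampling rate, Hz.
#' @param ramp_ms raised-cosine ramp duration (default 50 ms, the standard
#'   for 2-s modulation-detection stimuli).
#' @return A [waveform()].
#' @export
synth_fm_tone <- function(f_c, spec, dur, level_spl = 65, fs = 48000,
                          ramp_ms = 50) {
  stopifnot(inherits(spec, "modulation_spec"))
  if (spec$kind != "FM") stop("spec$kind must be 'FM'")
  if (spec$depth <= 0) stop("FM depth must be > 0")
  df <- spec$depth / 200            # single-sided excursion as a fraction
  if (f_c * (1 + df) >= fs / 2) stop("carrier excursion exceeds Nyquist")
  phi0 <- resolve_onset_phase(spec$onset_rule)
  n <- round(dur * fs)
  t <- (0:(n - 1)) / fs
  # integrate the instantaneous frequency analytically:
  # phase(t) = 2*pi*f_c*(t - df/(2*pi*f_m) * (cos(2*pi*f_m*t + phi0) - cos(phi0)))
  wm <- 2 * pi * spec$f_m
  phase <- 2 * pi * f_c * (t - df / wm * (cos(wm * t + phi0) - cos(phi0)))
  a <- spl_to_amp(level_spl)
  w <- waveform(a * sin(phase), fs = fs, level_spl = level_spl,
                channel_tag = "target-ear")
  apply_raised_cosine_ramp(w, ramp_ms)
}

#' Synthesize a sinusoidally amplitude-modulated tone
#'
#' Envelope `(1 + m*sin(2*pi*f_m*t + phi0))` on a fixed-frequency carrier.
#' The carrier amplitude is fixed at the quoted level (no compensation for
#' the modulation power; see the methods vignette for the rationale), so the
#' samples are scaled by `1/(1+m)` relative to full scale only if needed to
#' stay within bounds.
#'
#' @inheritParams synth_fm_tone
#' @param spec a [modulation_spec()] with `kind = "AM"`; `spec$depth` is
#'   `20*log10(m)` in dB.
#' @param phi0 optional fixed modulator starting phase (radians); overrides
#'   the onset rule when given.
#' @return A [waveform()].
#' @export
synth_am_tone <- function(f_c, spec, dur, level_spl = 65, fs = 48000,
                          ramp_ms = 50, phi0 = NULL) {
  stopifnot(inherits(spec, "modulation_spec"))
  if (spec$kind != "AM") stop("spec$kind must be 'AM'")
  m <- 10^(spec$depth / 20)
  if (m > 1 + 1e-12) stop("modulation index m must be <= 1")
  if (f_c >= fs / 2) stop("carrier above Nyquist")
  if (is.null(phi0)) phi0 <- resolve_onset_phase(spec$onset_rule)
  n <- round(dur * fs)
  t <- (0:(n - 1)) / fs
  env <- 1 + m * sin(2 * pi * spec$f_m * t + phi0)
  a <- spl_to_amp(level_spl)
  x <- a * env * sin(2 * pi * f_c * t)
  peak <- a * (1 + m)
  if (peak > 1) x <- x / peak       # clip guard; nominal level retained
  w <- waveform(x, fs = fs, level_spl = level_spl, channel_tag = "target-ear")
  apply_raised_cosine_ramp(w, ramp_ms)
}

#' Two-carrier AM dyad specification
#'
#' Two carriers at `center_freq * 2^(+/- separation_oct/2)`, each
#' sinusoidally amplitude-modulated. `"incoherent"` means exactly a
#' 180-degree modulator phase difference between the components.
#'
#' @param center_freq geometric center frequency, Hz (500, 1500 or 7000 in
#'   the standard conditions).
#' @param separation_oct carrier separation in octaves (2/3 or 4/3).
#' @param f_m modulation rate, Hz (2 or 20 in the standard conditions).
#' @param depth_db per-component AM depth, `20*log10(m)` dB.
#' @param phase_relation `"coherent"` or `"incoherent"`.
#' @return A `dyad_spec` list.
#' @export
dyad_spec <- function(center_freq, separation_oct, f_m, depth_db,
                      phase_relation = c("incoherent", "coherent")) {
  phase_relation <- match.arg(phase_relation)
  if (!separation_oct %in% c(2/3, 4/3))
    stop("separation_oct must be 2/3 or 4/3 octaves")
  structure(list(center_freq = center_freq, separation_oct = separation_oct,
                 f_m = f_m, depth_db = depth_db,
                 phase_relation = phase_relation), class = "dyad_spec")
}

#' Carrier frequencies of an AM dyad
#' @param spec a [dyad_spec()].
#' @return numeric length-2 vector, lower then upper carrier in Hz.
#' @export
dyad_carriers <- function(spec) {
  spec$center_freq * 2^(c(-1, 1) * spec$separation_oct / 2)
}

#' Synthesize an AM dyad
#'
#' Sum of two AM tones at equal per-component level. The common modulator
#' starting phase is randomized per presentation (drawn from the current
#' RNG state); the second component is phase-shifted by pi for incoherent
#' dyads.
#'
#' @param spec a [dyad_spec()].
#' @param dur duration, seconds.
#' @param fs sampling rate, Hz.
#' @param level_spl_component per-component nominal level, dB SPL
#'   (default 45).
#' @param ramp_ms raised-cosine ramps (default 50 ms).
#' @return A [waveform()] (diotic).
#' @export
synth_am_dyad <- function(spec, dur, fs = 48000, level_spl_component = 45,
                          ramp_ms = 50) {
  stopifnot(inherits(spec, "dyad_spec"))
  fc <- dyad_carriers(spec)
  if (any(fc >= fs / 2)) stop("dyad carrier above Nyquist")
  m <- 10^(spec$depth_db / 20)
  if (m > 1 + 1e-12) stop("modulation index m must be <= 1")
  phi_common <- stats::runif(1, 0, 2 * pi)
  dphi <- if (spec$phase_relation == "incoherent") pi else 0
  n <- round(dur * fs)
  t <- (0:(n - 1)) / fs
  a <- spl_to_amp(level_spl_component)
  x1 <- a * (1 + m * sin(2 * pi * spec$f_m * t + phi_common)) *
    sin(2 * pi * fc[1] * t)
  x2 <- a * (1 + m * sin(2 * pi * spec$f_m * t + phi_common + dphi)) *
    sin(2 * pi * fc[2] * t)
  x <- x1 + x2
  peak <- 2 * a * (1 + m)
  if (peak > 1) x <- x / peak
  w <- waveform(x, fs = fs, level_spl = level_spl_component,
                channel_tag = "diotic")
  apply_raised_cosine_ramp(w, ramp_ms)
}

# ERB of the auditory filter at frequency f (Hz); Glasberg & Moore form
#' Equivalent rectangular bandwidth of the auditory filter
#' @param f frequency in Hz.
#' @return ERB in Hz, `24.7 * (4.37 * f/1000 + 1)`.
#' @export
erb_hz <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Synthesize threshold-equalizing noise (TEN)
#'
#' Band-limited Gaussian noise spectrally shaped as `1/ERB(f)` in power so
#' that the level falling in one ERB is constant across the band, scaled so
#' the ERB centered on `center` carries `level_per_erb` dB SPL. Full
#' TEN(HL)-style K(f) detection-efficiency weighting is not applied; the
#' noise serves as a contralateral / spectral-gap masker.
#'
#' @param center band center frequency, Hz (band is
#'   `center * 2^(+/- bandwidth_oct/2)`).
#' @param bandwidth_oct total bandwidth in octaves (1, 1/3 or 1/6 in the
#'   standard conditions).
#' @param level_per_erb nominal level per ERB at the band center, dB SPL.
#' @param dur duration, seconds.
#' @param fs sampling rate, Hz.
#' @param ramp_ms onset/offset ramps (default 10 ms).
#' @return A [waveform()].
#' @export
synth_ten <- function(center, bandwidth_oct, level_per_erb, dur,
                      fs = 48000, ramp_ms = 10) {
  f_lo <- center * 2^(-bandwidth_oct / 2)
  f_hi <- center * 2^(bandwidth_oct / 2)
  if (f_hi >= fs / 2) stop("TEN band edge at or above Nyquist")
  n <- round(dur * fs)
  freqs <- (0:(n - 1)) * fs / n
  half <- freqs <= fs / 2
  # shape complex Gaussian spectrum: power density ~ 1/ERB(f) inside band
  amp <- numeric(n)
  in_band <- half & freqs >= f_lo & freqs <= f_hi
  amp[in_band] <- 1 / sqrt(erb_hz(freqs[in_band]))
  X <- amp * (stats::rnorm(n) + 1i * stats::rnorm(n))
  # hermitian symmetry for a real signal
  X[1] <- Re(X[1])
  if (n %% 2 == 0) X[n / 2 + 1] <- Re(X[n / 2 + 1])
  idx <- 2:ceiling(n / 2)
  X[n + 2 - idx] <- Conj(X[idx])
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  # scale: power within one ERB around `center` -> level_per_erb
  erb_lo <- center - erb_hz(center) / 2
  erb_hi <- center + erb_hz(center) / 2
  Xs <- stats::fft(x)
  pow <- Mod(Xs)^2 / n^2
  sel <- freqs >= erb_lo & freqs <= erb_hi & half
  p_erb <- 2 * sum(pow[sel])               # two-sided spectrum
  target <- 10^((level_per_erb - 100) / 10) / 2   # mean-square for RMS ref
  x <- x * sqrt(target / p_erb)
  if (max(abs(x)) > 1) x <- x / max(abs(x))
  w <- waveform(x, fs = fs, level_spl = level_per_erb,
                channel_tag = "contralateral")
  apply_raised_cosine_ramp(w, ramp_ms)
}

#' Assemble a forward-masking trial segment
#'
#' A 500-ms 1-kHz masker followed immediately (0-ms gap) by a 20-ms tone
#' pip, each with 10-ms raised-cosine ramps. The masker is diotic and the
#' pip monaural (target ear); the result is a two-channel waveform
#' (column 1 target ear, column 2 contralateral).
#'
#' @param masker_level masker level, dB SPL.
#' @param pip_freq pip frequency; one of 800, 860, 920, 980, 1020, 1080,
#'   1140, 1200 Hz.
#' @param pip_level pip level, dB SPL; `-Inf` renders a silent reference
#'   segment.
#' @param fs sampling rate, Hz.
#' @return A binaural [waveform()] of duration 520 ms.
#' @export
assemble_forward_masking_trial <- function(masker_level, pip_freq, pip_level,
                                           fs = 48000) {
  pip_freqs <- c(800, 860, 920, 980, 1020, 1080, 1140, 1200)
  if (!pip_freq %in% pip_freqs)
    stop("unsupported pip frequency; must be one of 800..1200 Hz set")
  n_mask <- round(0.5 * fs)
  n_pip <- round(0.02 * fs)
  t_mask <- (0:(n_mask - 1)) / fs
  masker <- spl_to_amp(masker_level) * sin(2 * pi * 1000 * t_mask)
  masker <- apply_raised_cosine_ramp(
    waveform(masker, fs, masker_level, "diotic"), 10)$samples
  if (is.finite(pip_level)) {
    t_pip <- (0:(n_pip - 1)) / fs
    pip <- spl_to_amp(pip_level) * sin(2 * pi * pip_freq * t_pip)
    pip <- apply_raised_cosine_ramp(
      waveform(pip, fs, pip_level, "target-ear"), 10)$samples
  } else {
    pip <- numeric(n_pip)
  }
  target <- c(masker, pip)
  contra <- c(masker, numeric(n_pip))
  waveform(cbind(target = target, contra = contra), fs = fs,
           level_spl = masker_level, channel_tag = "binaural")
}
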