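test_that("raised-cosine ramps: identity, midpoint gain, Hann-integral equivalence", {
  fs <- 48000
  dc <- waveform(rep(0.5, 2 * fs), fs, 65)
  expect_identical(apply_raised_cosine_ramp(dc, 0)$samples, dc$samples)

  # 2-s tone with 50-ms ramps: the envelope at exactly 25 ms is the raised
  # cosine midpoint, gain 0.5
  ramped <- apply_raised_cosine_ramp(dc, 50)
  i_25ms <- round(0.025 * fs) + 1
  expect_equal(ramped$samples[i_25ms] / 0.5, 0.5, tolerance = 1e-3)
  # interior untouched, duration unchanged
  expect_equal(length(ramped$samples), length(dc$samples))
  expect_identical(ramped$samples[round(0.5 * fs)], 0.5)

  # 20-ms pip with 10-ms ramps: envelope is a full Hann window; integrals
  # agree with a directly computed periodic Hann window
  n <- round(0.02 * fs)
  pip <- apply_raised_cosine_ramp(waveform(rep(1, n), fs, 65), 10)
  hann <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))   # symmetric Hann
  expect_equal(sum(pip$samples), sum(hann), tolerance = 2e-3)

  expect_error(apply_raised_cosine_ramp(waveform(rep(1, 100), fs, 65), 10),
               "ramp longer")
})

test_that("FM tones have the stated excursion, flat envelopes, and demodulate correctly", {
  fs <- 48000
  # excursion 5.02% of 1 kHz spans [974.9, 1025.1] Hz
  spec <- modulation_spec("FM", f_m = 2, depth = 5.02, onset_rule = "increasing")
  w <- synth_fm_tone(1000, spec, dur = 2, level_spl = 65, fs = fs)
  keep <- (0.2 * fs):(1.8 * fs)   # exclude ramps
  fi <- instantaneous_frequency(w)[keep]
  expect_equal(min(fi), 1000 * (1 - 0.0251), tolerance = 2e-3)
  expect_equal(max(fi), 1000 * (1 + 0.0251), tolerance = 2e-3)

  # flat Hilbert envelope in the steady state (< 0.2 dB ripple)
  env <- hilbert_envelope(w)[keep]
  expect_lt(20 * log10(max(env) / min(env)), 0.2)

  # near-zero depth: spectral peak within one FFT bin of the carrier
  sp0 <- modulation_spec("FM", f_m = 2, depth = 1e-4, onset_rule = "increasing")
  w0 <- synth_fm_tone(1000, sp0, dur = 1, level_spl = 65, fs = fs)
  pk <- which.max(Mod(stats::fft(w0$samples))[1:(fs / 2)])
  expect_lt(abs((pk - 1) * fs / length(w0$samples) - 1000), 1.5)

  # phase-derivative demodulation of a 20-Hz, 5% FM recovers a 20-Hz
  # sinusoid with 50-Hz peak-to-peak excursion within 1%
  sp5 <- modulation_spec("FM", f_m = 20, depth = 5, onset_rule = "increasing")
  w5 <- synth_fm_tone(1000, sp5, dur = 2, fs = fs)
  fi5 <- instantaneous_frequency(w5)[keep]
  expect_equal(max(fi5) - min(fi5), 50, tolerance = 0.01)
  zc <- diff(sign(fi5 - 1000))
  cycles <- sum(zc != 0) / 2
  expect_equal(cycles / (length(keep) / fs), 20, tolerance = 0.05)

  expect_error(modulation_spec("FM", 2, depth = 0), "depth")
})

test_that("AM tones carry the specified envelope depth on a fixed carrier", {
  fs <- 48000
  # -8 dB depth: m ~ 0.398, envelope max/min ratio ~ 7.3 dB
  spec <- modulation_spec("AM", f_m = 5, depth = -8, onset_rule = "increasing")
  w <- synth_am_tone(1000, spec, dur = 2, fs = fs)
  keep <- (0.3 * fs):(1.7 * fs)
  env <- hilbert_envelope(w)[keep]
  m <- 10^(-8 / 20)
  expect_equal(20 * log10(max(env) / min(env)),
               20 * log10((1 + m) / (1 - m)), tolerance = 0.05)
  # carrier frequency constant: phase-derivative deviation < 0.1%
  fi <- instantaneous_frequency(w)[keep]
  expect_lt(max(abs(fi - 1000)) / 1000, 1e-3)

  # m = 1 at a slow rate: envelope minimum < 1% of maximum
  sp1 <- modulation_spec("AM", f_m = 2, depth = 0, onset_rule = "increasing")
  w1 <- synth_am_tone(500, sp1, dur = 2, fs = fs)
  env1 <- hilbert_envelope(w1)[keep]
  expect_lt(min(env1), 0.01 * max(env1))

  expect_error(modulation_spec("AM", 5, depth = 1), "m in")
})

test_that("AM dyads: closed-form carriers and envelope (in)coherence", {
  fs <- 48000
  sp <- dyad_spec(1500, 2/3, f_m = 20, depth_db = -6, "incoherent")
  expect_equal(dyad_carriers(sp), 1500 * 2^(c(-1, 1) / 3))

  set.seed(11)
  w_in <- synth_am_dyad(dyad_spec(1500, 2/3, 20, -6, "incoherent"), dur = 1,
                        fs = fs)
  w_co <- synth_am_dyad(dyad_spec(1500, 2/3, 20, -6, "coherent"), dur = 1,
                        fs = fs)
  keep <- (0.2 * fs):(0.8 * fs)
  env_corr <- function(w) {
    fc <- 1500 * 2^(c(-1, 1) / 3)
    e1 <- placefm:::band_envelope(w$samples, fs, fc[1])[keep]
    e2 <- placefm:::band_envelope(w$samples, fs, fc[2])[keep]
    stats::cor(e1 - mean(e1), e2 - mean(e2))
  }
  expect_lt(env_corr(w_in), -0.9)
  expect_gt(env_corr(w_co), 0.9)

  expect_error(dyad_spec(1500, 1/2, 20, -6), "separation")
})

test_that("TEN is band-limited with flat per-ERB level at the stated value", {
  fs <- 48000
  band_level_db <- function(w, lo, hi) {
    n <- length(w$samples)
    pow <- Mod(stats::fft(w$samples))^2 / n^2
    freqs <- (0:(n - 1)) * fs / n
    sel <- freqs >= lo & freqs <= hi & freqs <= fs / 2
    10 * log10(2 * sum(pow[sel]) * 2) + 100   # re: full-scale sine RMS
  }
  set.seed(5)
  w <- synth_ten(1000, 1, level_per_erb = 39, dur = 1, fs = fs)
  # energy outside the octave band at least 40 dB below in-band
  in_band <- band_level_db(w, 1000 / sqrt(2), 1000 * sqrt(2))
  out_band <- band_level_db(w, 1600, 20000)
  expect_gt(in_band - out_band, 40)

  # 1/3-octave TEN: measured level in the ERB at band center = 39 +/- 0.5 dB
  w3 <- synth_ten(1000, 1/3, level_per_erb = 39, dur = 1, fs = fs)
  erb <- erb_hz(1000)
  lev <- band_level_db(w3, 1000 - erb / 2, 1000 + erb / 2)
  expect_equal(lev, 39, tolerance = 0.5)

  # per-ERB spectral level is duration-invariant (stationarity)
  w6 <- synth_ten(1000, 1/3, level_per_erb = 39, dur = 2, fs = fs)
  lev6 <- band_level_db(w6, 1000 - erb / 2, 1000 + erb / 2)
  expect_equal(lev6, lev, tolerance = 0.5)

  expect_error(synth_ten(20000, 1, 39, 0.5, fs = fs), "Nyquist")
})

test_that("forward-masking trials assemble masker and pip with a 0-ms gap", {
  fs <- 48000
  w <- assemble_forward_masking_trial(65, 1020, 40, fs = fs)
  n_expect <- round(0.52 * fs)     # 500 ms masker + 20 ms pip
  expect_equal(nrow(w$samples), n_expect)
  n_mask <- round(0.5 * fs)
  # pip onset directly at masker offset (0-ms gap, within one sample)
  pip_seg <- w$samples[(n_mask + 1):n_expect, "target"]
  expect_gt(max(abs(pip_seg)), 0)
  expect_equal(w$samples[(n_mask + 1):n_expect, "contra"],
               rep(0, n_expect - n_mask))
  # masker is diotic
  expect_identical(w$samples[1:n_mask, "target"], w$samples[1:n_mask, "contra"])

  # silent reference: second segment is silence
  w0 <- assemble_forward_masking_trial(65, 1020, -Inf, fs = fs)
  expect_identical(w0$samples[(n_mask + 1):n_expect, "target"],
                   rep(0, n_expect - n_mask))

  expect_error(assemble_forward_masking_trial(65, 1000, 40), "unsupported")
})

test_that("synthesis is reproducible bit-exactly given a seed, and WAV export round-trips", {
  set.seed(99)
  a <- synth_am_dyad(dyad_spec(500, 4/3, 2, -10, "incoherent"), dur = 0.25)
  set.seed(99)
  b <- synth_am_dyad(dyad_spec(500, 4/3, 2, -10, "incoherent"), dur = 0.25)
  expect_identical(a$samples, b$samples)

  tf <- tempfile(fileext = ".wav")
  write_wav(a, tf, format = "float32")
  back <- read_wav(tf)
  expect_equal(back$samples, a$samples, tolerance = 1e-7)
  expect_equal(back$fs, a$fs)

  write_wav(a, tf, format = "pcm24")
  back24 <- read_wav(tf)
  expect_lt(max(abs(back24$samples - a$samples)), 2^-22)  # 24-bit quantization

  expect_equal(stimulus_filename("fm", 1000, 2, 5.02, 7),
               "fm_1000_2_5.02_7.wav")
})
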