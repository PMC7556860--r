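---
title: "Methods: place coding, adaptive psychophysics, and the inference chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: place coding, adaptive psychophysics, and the inference chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placefm)
```

# The scientific problem

Frequency modulation (FM) of a pure tone produces no change in the
stimulus envelope, but it sweeps the tone's position along the cochlea's
tonotopic axis. At any fixed cochlear place away from the carrier, that
sweep appears as a periodic change in output level — FM is converted to
amplitude modulation (AM) by the slopes of cochlear filtering. Whether
human FM sensitivity at slow modulation rates relies on this *place code*
or on spike-timing (phase-locking) cues has been a long-standing question.
`placefm` packages the quantitative tools needed to study it: a minimal
excitation-pattern model, synthesis of the relevant stimuli, simulation of
the adaptive psychophysical procedures, a synthetic-cohort generator, and
the complete statistics chain for the two experiment designs involved (an
individual-differences study across a hearing-loss continuum, and an
AM-dyad study in normal-hearing listeners).

# The excitation-pattern (place) model

The model is deliberately the simplest quantitative reading of the
place-coding schematic: the excitation pattern is **triangular in dB
versus log2 frequency**, parameterized directly by the two behavioral
masking-function slopes (dB/octave). No gammatone or rounded-exponential
filterbank stands behind it; the correlational logic of the study design
operates on the behavioral slopes themselves, so the model does too.

For a peak-to-peak excursion of $2\Delta f$ (as a percentage of the
carrier), the excursion spans

$$\Delta_{oct} = \log_2\!\frac{1 + \Delta f}{1 - \Delta f},
\qquad \Delta f = \frac{2\Delta f(\%)}{200},$$

octaves, and the peak-to-peak level change on each side of the pattern is
$|s| \cdot \Delta_{oct}$ dB for side slope $s$. AM depth, by contrast,
passes through any dB-linear pattern unchanged — the model's signature
dissociation (`am_place_response()` is the identity in depth and invariant
in the slopes).

`predict_fm_threshold()` inverts the map in closed form: the smallest
excursion whose **dominant-side** level change reaches a criterion
$c \cdot \mathrm{eff}$ dB. The dominant-side (max) rule is the default
because the steeper low-frequency slope is predicted to dominate FM
detection; a quadrature combination rule is available as an option. The
detection criterion $c$ is a free calibration parameter — the source
design never states one — and the cohort generator uses $c = 0.5$ dB
(slow rate) and $c = 1$ dB (fast rate), chosen once so that median
predicted thresholds land on the typical published FM-difference-limen
scale (tenths of a percent to a few percent) with slow-rate sensitivity
better than fast-rate, and not revisited.

# Stimulus synthesis

All stimuli are synthesized at 48 kHz with raised-cosine ramps (10 ms for
tones/pips, 50 ms for 2-s modulation stimuli). Level convention: a
full-scale sinusoid corresponds to a nominal 100 dB SPL; absolute hardware
calibration is out of scope. Specific choices:

* **FM tones** integrate the instantaneous-frequency trajectory
  analytically, so the modulator phase is exact and the Hilbert envelope is
  flat to well under 0.2 dB.
* **AM tones** keep the carrier amplitude fixed at the quoted level (the
  level is quoted pre-modulation). The alternative — RMS compensation for
  the modulation power $1 + m^2/2$ — is not applied, because the source
  methods do not state it; at threshold depths the difference is a small
  fraction of a dB.
* **AM dyads** place two carriers at $f_c \cdot 2^{\pm s/2}$ ($s$ = 2/3 or
  4/3 octaves), each AM'd at the same rate; "incoherent" means exactly a
  180° modulator phase difference, and the common starting phase is
  randomized per presentation.
* **Threshold-equalizing noise (TEN)** is Gaussian noise shaped in the
  frequency domain as $1/\mathrm{ERB}(f)$ in power, with
  $\mathrm{ERB}(f) = 24.7\,(4.37 f/1000 + 1)$ Hz, so the level per ERB is
  flat across the band; it is scaled so the ERB at the band center carries
  the stated dB SPL. The full TEN(HL) detection-efficiency weighting
  $K(f)$ is intentionally omitted: in these designs the noise only
  prevents off-frequency listening or audible cross-talk.
* **Forward-masking trials** concatenate a 500-ms diotic 1-kHz masker and
  a 20-ms monaural tone pip with a 0-ms gap, each ramped 10 ms.

WAV export (`write_wav()`, PCM-24 or float32) is provided for every
stimulus class; synthesis is bit-reproducible given parameters and seed.

# Adaptive staircases

`run_staircase()` implements the transformed up-down family: the value
moves down after $k$ consecutive correct responses, up after any error,
converging on the stimulus value where $p^k = 0.5$ — 79.4% correct for
3-down-1-up, 70.7% for 2-down-1-up. Edge conventions the source text does
not pin down were fixed as the standard ones: reversal counting starts at
the first direction change; the step size switches the moment a schedule
segment's reversal quota is filled; thresholds are the (geometric or
arithmetic) mean of the final six reversal values. FM tracks are
multiplicative (log domain, factors 2/1.4/1.19 from a 5.02% start); AM and
level tracks are additive in dB. Bounds clamp the track (AM depth at 0 dB,
i.e. $m = 1$; excursion at 100%; levels at 105 dB SPL); the
AM-phase-discrimination screening uses the published early-stop rule
(15 presentations at the depth ceiling abort the run with no threshold).

Simulated observers are cumulative Gaussians in transformed stimulus units
($10\log_{10}$ of excursion for FM-type tracks, raw dB otherwise) with
guess rate $1/n_{alternatives}$ and an optional lapse rate.

**A property worth knowing:** the reversal-mean estimator of a short
published run (nine or ten reversals, coarse initial steps, start value
well above threshold) carries a small systematic offset relative to the
rule's asymptotic point. In long stationary tracks the package's
simulations recover the 79.4%/70.7% points to within ~0.1 dB, but with the
published schedules and start values the Monte-Carlo mean threshold sits
slightly high for the 3-down-1-up FM task (tracked percent correct ≈ 81
rather than 79.4) and 1–2 dB low for the 2-down-1-up screening task
(≈ 66–67 rather than 70.7, because the 8-dB descent from 40 dB SPL
overshoots below threshold and six 2-dB reversals only partly recover).
This is a property of the procedure itself, reproduced — not introduced —
by the simulation.

# The synthetic cohort generator

`generate_cohort()` emulates the individual-differences study population:

* **Hearing loss** (1-kHz absolute threshold) uniform on [0, 70) dB SPL,
  mirroring the deliberate recruitment for an even threshold spread; ears
  at 70 dB SPL or more are excluded by construction.
* **Age** increases with hearing loss (intercept 45 y, 0.45 y/dB, SD 8 y,
  clamped to 19–79 y). The true joint age x loss distribution is not
  published; these values make the cohort mostly older with a plausible
  young tail and are documented assumptions, not estimates.
* **Masking slopes** are linear in hearing loss with population
  correlations −0.7 (low side) and +0.7 (high side) and means 49.4 and
  −23.3 dB/octave. The slope noise is *heteroscedastic*: its SD tapers
  linearly with hearing loss (factor 0.3 at 70 dB relative to 0 dB),
  rescaled so the marginal variance — and hence the configured population
  correlation — is preserved. Rationale: broad, shallow filters vary less
  across impaired ears than sharp ones do across normal ears (the funnel
  shape seen in such scatter plots), and it keeps simulated masked
  thresholds inside the measurable range between the masker level and the
  pip's absolute threshold, where the published regression logic operates.
* **FM thresholds** come from the place model (dominant-side rule) plus a
  shared log-normal *efficiency* latent (SD 2 dB on the 10log/20log
  threshold scale), a small age effect, and residual noise; the efficiency
  latent loads more on fast FM (0.8) than slow FM (0.3). **AM thresholds**
  are driven by the same efficiency latent plus age and noise. This single
  shared latent reproduces the study's collinearity structure: slow and
  fast FM strongly correlated through the shared slopes, slow and fast AM
  correlated near 0.6 through efficiency, and slow FM only weakly tied to
  AM.
* **Measurement**: each modulation threshold is re-measured through three
  simulated staircase runs (observer spread 3 dB, 1% lapses), with the
  published data-quality rule (run SD ≥ 4 → three replacement runs).
  Masked thresholds at the eight pip frequencies are the triangular
  pattern anchored at the masker level, plus 2 dB run noise, floored at
  the pip's absolute threshold, two runs each (SD ≥ 4 → two replacement
  runs); slopes are then re-fitted by the same regression the analysis
  uses.

What the generator does **not** emulate: audiogram shapes away from 1 kHz,
conductive losses, per-ear duplicate testing (the worse-ear rule is
reduced to a flag), training/learning effects, and any non-Gaussian
structure of real threshold noise. Passing recovery tests on this cohort
shows the *pipeline* is consistent — it does not validate the physiological
assumptions against real listeners.

`generate_exp2_cohort()` uses an explicit cell-mean template for the
AM-dyad tasks: a product-form center x rate interaction giving slow-rate
advantages of 2 and 3 dB at 500 and 1500 Hz and none at 7000 Hz (scalable
to zero via `interaction_scale`, which is how the type-I calibration tests
work), a separation effect larger at the outer center frequencies, subject
random intercepts, and per-run noise. Detection performance is simulated
at the trial level: 100 Bernoulli trials at $p = \Phi(d'/\sqrt2)$ per
cell, re-converted through the same $d' = \sqrt2\,z(p_c)$ transform the
analysis uses (the printed form of that equation in the source is
typographically garbled; the $\sqrt2$ form follows the cited standard
reference).

# The statistics chain

All threshold statistics operate on $10\log_{10}(2\Delta f\,\%)$ for FM
and $20\log_{10} m$ for AM. Conventions, fixed once:

* Correlations are one-tailed in declared directions (steeper low slope ↔
  better FM ⇒ negative; two-tailed only where a comparison has no
  prediction), with two-sided 95% CIs from the Fisher transform,
  $\tanh(\mathrm{atanh}\,r \pm 1.96/\sqrt{n-3})$. This CI convention
  reproduces the published interval $[-0.804, -0.513]$ for $r = -0.685$,
  $n = 55$ exactly at printed precision, which is how it was validated.
* Holm families follow the declared design families (2 for the
  loss-vs-slope pair, 6 for the modulation intercorrelations, 8 for the
  FM-slope zero-order + partial set, 4 for the AM-slope set). The
  adjustment is the standard step-down with monotonicity enforcement
  (`stats::p.adjust`); note it is not idempotent under re-application,
  as no step-down adjustment is.
* Partial correlations residualize on age, 1-kHz threshold, and the
  rate-matched AM threshold; p and CI use df reduced by the number of
  covariates ($n - 2 - k$; Fisher SE $1/\sqrt{n - 3 - k}$). When only the
  published residual files are available (they carry no age column), the
  residual columns are correlated directly with the same reduced-df
  convention.
* Dependent overlapping correlations are compared with Dunn & Clark's Z
  using Steiger's pooled-correlation modification.
* The hierarchical OLS enters 1-kHz threshold, age, rate-matched AM, low
  slope, high slope — in that order (slopes last is the conservative
  choice); incremental $R^2$ sums to the full-model $R^2$ by construction,
  coefficient p-values come from the full model, and collinearity is
  monitored by VIF. A slopes-first ordering is also reported, whose first
  increment equals the squared zero-order correlation.
* The bootstrap test-retest simulation draws 3 + 3 runs per subject
  (2 + 2 and four regressions per iteration for the masking slopes) from
  per-subject normal distributions, correlates phase means across
  subjects, and Fisher-z-averages across iterations (default $10^5$;
  $10^4$ for quick checks). With $k$ runs per phase it converges on the
  classical reliability $\sigma^2_{BS} / (\sigma^2_{BS} +
  \sigma^2_{WS}/k)$, which is the closed form the tests check against.
* The repeated-measures ANOVAs are type III over fully-within designs
  (built on `car::Anova`), with Mauchly's test per effect at α = .05
  triggering the Greenhouse-Geisser correction. Simple effects are paired
  contrasts Holm-adjusted within the declared family.

# Numerical and scale choices

Problem sizes in the test suite were chosen as the smallest that make the
statistical assertions stable: 2,000 staircase runs for convergence checks
(Monte-Carlo SE well under the 5% tolerance), 100 seeded cohorts of n = 55
for parameter recovery, 1,000 null cohorts for type-I calibration of the
interaction test, and $10^4$ bootstrap iterations against the closed-form
reliability (±0.02). Degenerate inputs are defined rather than left to
chance: zero-variance correlations and empty Holm families are errors;
both-slopes-zero returns a "no place cue" sentinel that the cohort
generator maps to a threshold ceiling (30% excursion); constant ANOVA
responses return F = 0; d-prime clamps proportions at $1/(2n)$;
staircases that never reverse (perfect or hopeless observers) terminate
at the trial cap with an undefined threshold rather than a fabricated one.

# Known limitations

The place model is static and linear in dB: no compression, suppression,
or level-dependent tuning, and no off-frequency listening strategy beyond
the dominant-side rule. The observer model has a fixed psychometric spread
across tasks. The cohort's correlation targets are population values —
any single n = 55 draw scatters around them, and the masked-threshold
floor plus measurement noise attenuate recovered correlations slightly
(recovered means ≈ −0.73 / +0.63 for configured ∓0.7 under default
conditions). The human-sample statistics themselves are reproducible only
from the per-subject source-data files distributed with the original
figures; `analyze_exp1()` accepts those files directly when present.
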