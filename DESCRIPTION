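Package: placefm
Title: Place-Coding Models, Adaptive Psychophysics, and Statistics for FM and AM Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying the role of cochlear place coding in the
    perception of frequency modulation (FM). Synthesizes FM/AM tones, AM
    dyads, threshold-equalizing noise and forward-masking trials; implements
    a triangular excitation-pattern model that converts FM excursion into
    off-frequency level fluctuations; simulates transformed up-down adaptive
    staircases against parametric observers; generates synthetic listener
    cohorts with configurable hearing loss, masking-slope and modulation
    sensitivity structure; estimates masking-function slopes by linear
    regression; and provides the full inference chain used in individual-
    differences studies of modulation perception (one-tailed Pearson and
    partial correlations with Fisher-z confidence intervals, Holm families,
    Steiger's test for dependent correlations, hierarchical OLS variance
    decomposition with variance inflation factors, bootstrap test-retest
    reliability simulation, and repeated-measures ANOVA with
    Greenhouse-Geisser correction and d-prime conversion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
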