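# Adaptive-track registry for the standard tasks.
# steps are multiplicative factors (step_mode: factor) or dB offsets
# (step_mode: db); n_reversals gives the reversal quota per schedule row.
fm_1kHz:
  rule: 3-down-1-up
  n_alternatives: 2
  steps: [2.0, 1.4, 1.19]
  n_reversals: [2, 2, 6]
  start_value: 5.02          # peak-to-peak excursion, % of carrier
  step_mode: factor
  threshold_rule: geometric-mean
  bounds: [1.0e-4, 100]
  early_stop: ~
am_1kHz:
  rule: 3-down-1-up
  n_alternatives: 2
  steps: [6, 2, 1]
  n_reversals: [2, 2, 6]
  start_value: -8            # 20log10(m), dB
  step_mode: db
  threshold_rule: arithmetic-mean
  bounds: [-60, 0]
  early_stop: ~
abs_1kHz:
  rule: 3-down-1-up
  n_alternatives: 2
  steps: [8, 4, 2]
  n_reversals: [1, 2, 6]
  start_value: 40            # dB SPL
  step_mode: db
  threshold_rule: arithmetic-mean
  bounds: [-20, 105]
  early_stop: ~
pip_quiet:
  rule: 3-down-1-up
  n_alternatives: 2
  steps: [8, 4, 2]
  n_reversals: [2, 2, 6]
  start_value: 40
  step_mode: db
  threshold_rule: arithmetic-mean
  bounds: [-20, 105]
  early_stop: ~
forward_masking:
  rule: 3-down-1-up
  n_alternatives: 2
  steps: [8, 4, 2]
  n_reversals: [2, 2, 6]
  start_value: 55            # masker level - 10 dB by convention
  step_mode: db
  threshold_rule: arithmetic-mean
  bounds: [-20, 105]
  early_stop: ~
exp2_discrim:
  rule: 2-down-1-up
  n_alternatives: 3
  steps: [6, 2, 1]
  n_reversals: [2, 2, 6]
  start_value: -8
  step_mode: db
  threshold_rule: arithmetic-mean
  bounds: [-60, 0]
  early_stop:
    bound: upper
    max_hits: 15
exp2_am_detect:
  rule: 3-down-1-up
  n_alternatives: 2
  steps: [6, 2, 1]
  n_reversals: [2, 2, 6]
  start_value: -8
  step_mode: db
  threshold_rule: arithmetic-mean
  bounds: [-60, 0]
  early_stop: ~
exp2_abs_screen:
  rule: 2-down-1-up
  n_alternatives: 3
  steps: [8, 4, 2]
  n_reversals: [1, 2, 6]
  start_value: 40
  step_mode: db
  threshold_rule: arithmetic-mean
  bounds: [-20, 105]
  early_stop: ~
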