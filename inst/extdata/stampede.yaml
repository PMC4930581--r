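# Six-arm four-stage prostate-cancer design: failure-free survival at the
# three interim analyses, overall survival at the final analysis.
design:
  n_stages: 4
  n_arms: 5
  allocation_ratio: 0.5
  alpha: [0.500, 0.250, 0.100, 0.025]
  omega: [0.95, 0.95, 0.95, 0.90]
  control_events: [113, 216, 334, 403]
  effects:
    scale: hr
    target_I: 0.75
    target_D: 0.75
    null_I: 1.0
    null_D: 1.0
  i_equals_d: false
  binding: true
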