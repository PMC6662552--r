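seed: 42
n_generations: 1
cohort:
  n_per_cell: 24
  seed: 42
tracking:
  threshold_px: 5
  interval_s: 2
  window_s: 90
  offset_s: 10
  polarity: dark
  n_sequences: 2
scoring:
  direction: post_minus_pre
  require_complete: true
selection:
  cap: 10
stats:
  nboot_repeatability: 50
  nboot_ci: 200
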