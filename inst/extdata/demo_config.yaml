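# Bundled synthetic demonstration configuration: a 40x40 cell scene over
# five census years with 8 zones, dominant cultivated->construction
# conversion, and a small quantile-regression stage.
mode: synthetic
seed: 42
landscape:
  grid_shape: [40, 40]
  n_zones: 8
balance_mode: normalized
level_k: 5
balance_k: 7
demand:
  log_base: 10
  nlci_scale: 100
  p_floor: 1
  nlci_floor: 1
regression:
  n_zones: 120
  beta: [0.5, -8.0, -5.0, -12.0, -2.0, -2.0, 6.0, 1.0, -0.5, -0.3, 0.7]
  noise_sd: 0.1
  theta_grid: [0.1, 0.3, 0.5, 0.7, 0.9]
  boot_reps: 60
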