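# Run configuration for an ovarian-tumor-like development study:
# 7 candidate predictors, 7 model parameters, ~33% event fraction.
outcome: "y"
predictors:
  - {name: age, type: continuous, spline: true, forced: true}
  - {name: lesion_diam, type: continuous, spline: true}
  - {name: solid_diam, type: continuous, spline: true}
  - {name: papillations, type: continuous}   # count score 0-4
  - {name: acoustic_shadows, type: binary}
  - {name: ascites, type: binary}
  - {name: bilateral, type: binary}
strategy:
  estimator: mle
  use_splines: false
  selection: none
  imputation: none
accrual: {n_start: 100, n_add: 50, n_max: 3000, B: 200}
rules:
  - {name: rule1, slope_min: 0.9, optimism_max: 0.02, consecutive: 2}
  - {name: rule2, slope_min: 0.9, optimism_max: 0.01, consecutive: 2}
seed: 1
# Anticipated Cox-Snell R-squared for the initial fixed-size estimate N0.
# This is a user-supplied planning input, not a package constant: argue it
# from prior knowledge of the modeling context before data collection.
fixed_size: {r2cs: 0.45, S: 0.9}
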