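# Run configuration for a coronary-artery-disease-like development study:
# 11 candidate predictors (12 model parameters), ~44% event fraction,
# missing values in five predictors handled by single stochastic imputation.
outcome: "y"
predictors:
  - {name: age, type: continuous, spline: true, forced: true}
  - {name: hdl, type: continuous, spline: true}
  - {name: ldl, type: continuous, spline: true}
  - {name: log_fibrinogen, type: continuous, spline: true}
  - {name: sex_male, type: binary, forced: true}
  - {name: chest_pain, type: binary}
  - {name: diabetes, type: binary}
  - {name: hypertension, type: binary}
  - {name: dyslipidaemia, type: binary}
  - {name: crp_high, type: binary}
  - {name: smoking, type: categorical, levels: [never, former, current]}
strategy:
  estimator: mle
  use_splines: false
  selection: none
  imputation: single_fcs
accrual: {n_start: 100, n_add: 50, n_max: 3000, B: 200}
rules:
  - {name: rule1, slope_min: 0.9, optimism_max: 0.02, consecutive: 2}
  - {name: rule2, slope_min: 0.9, optimism_max: 0.01, consecutive: 2}
seed: 1
# Anticipated Cox-Snell R-squared for the initial fixed-size estimate N0
# (user-supplied planning input; see the methods vignette).
fixed_size: {r2cs: 0.20, S: 0.9}
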