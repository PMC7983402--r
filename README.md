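# adaptsize

Adaptive sample size determination for developing clinical prediction
models with a binary outcome.

## The problem

How many patients does a risk prediction model need? Rules of thumb (10
events per candidate parameter, EPP) and fixed a-priori calculations
(minimum-sample-size criteria based on the anticipated Cox–Snell R²) pick
one number before any data exist. `adaptsize` implements the complementary
*adaptive* approach for researchers planning diagnostic or prognostic
model studies: accrue patients in batches, internally validate the interim
model at every step with Harrell's enhanced bootstrap, and stop once
prespecified performance targets hold.

Two optimism-focused measures drive the stopping rules:

- **calibration slope** — the coefficient of a logistic regression of the
  outcome on the model's linear predictor; a slope below 1 means the
  estimated risks are too extreme (overfitting);
- **AUC optimism** — apparent minus bootstrap-corrected c-statistic.

The default rules require a corrected slope ≥ 0.9 together with AUC
optimism ≤ 0.02 (rule 1) or ≤ 0.01 (rule 2), on two consecutive
assessments (inclusive thresholds). The enhanced bootstrap re-runs the
*complete* modeling strategy — spline knot estimation, variable selection,
imputation — inside every replicate: optimism per measure is
`mean(PM_B − PM_O)` over replicates and corrected performance is apparent
performance minus that optimism.

The package bundles:

- four prespecified modeling strategies: maximum-likelihood logistic
  regression, 3-knot restricted cubic splines, Firth's penalized
  likelihood (finite under separation), and backward elimination with
  forced predictors (`strategy_spec()`, `fit_strategy()`);
- fixed a-priori calculators (`epp_sample_size()`, `riley_min_n()`,
  `round_to_batch()`);
- the adaptive engine (`run_adaptive()`, `stopping_rule()`,
  `accrual_config()`);
- two synthetic case-study generators with calibrated event fraction and
  population AUC, including realistic missingness and chained-equations
  imputation (`ovarian_like_scenario()`, `cad_like_scenario()`,
  `fcs_impute_single()`, `mi_in_bootstrap()`);
- a resampling-study harness producing learning curves with holdout
  checks (`run_study()`).

## Worked example

Plan a study resembling an ovarian-tumor diagnosis model: 7 candidate
parameters, ~33% event fraction.

```r
library(adaptsize)

fixed_size_table(p = 7, phi = 0.33, r2cs = 0.45, epp = c(10, 20))
#>                         method   n n_batched epp_implied
#> 1                       10 EPP 213       250          10
#> 2                       20 EPP 425       450          20
#> 3 min-n criteria (r2cs = 0.45) 340       350          16
```

10 EPP suggests ~213 patients; the Cox–Snell criteria (with a
user-supplied anticipated R² of 0.45) suggest 340, i.e. recruitment to
350 when accruing in batches of 50. Now monitor adaptively on a synthetic
population with that case mix:

```r
cfg <- calibrate_scenario(ovarian_like_scenario())
pop <- generate_population(cfg, n = 2000, seed = 42)
pop
#> patient_table: 2000 patients, 640 events ( 32.0% )
#> predictors: age, lesion_diam, solid_diam, papillations, acoustic_shadows, ascites, bilateral

rules <- list(stopping_rule(0.9, 0.02, name = "rule1"),
              stopping_rule(0.9, 0.01, name = "rule2"))
lc <- run_adaptive(pop, strategy_spec("mle"),
                   accrual_config(n_start = 100, n_add = 50, n_max = 600,
                                  B = 200),
                   rules, seed = 7)
lc
#> learning_curve: 11 assessments, n = 100 to 600
#>   rule rule1 : stop at n = 400
#>   rule rule2 : stop at n = 400

round(lc$assessments[, c("n", "events", "epp", "auc_corrected",
                         "auc_optimism", "slope_corrected")], 3)
#>      n events    epp auc_corrected auc_optimism slope_corrected
#> 1  100     30  4.286         0.875        0.029           0.785
#> 2  150     45  6.429         0.898        0.018           0.831
#> 3  200     61  8.714         0.912        0.011           0.899
#> 4  250     80 11.429         0.898        0.014           0.874
#> 5  300     94 13.429         0.906        0.010           0.892
#> 6  350    112 16.000         0.920        0.006           0.919
#> 7  400    123 17.571         0.916        0.007           0.927
#> 8  450    138 19.714         0.914        0.007           0.927
#> 9  500    155 22.143         0.917        0.006           0.946
#> 10 550    172 24.571         0.905        0.006           0.949
#> 11 600    189 27.000         0.909        0.005           0.957
```

At n = 100 the model is visibly overfit (corrected slope 0.785, optimism
0.029). Both measures improve as data accrue; the slope ≥ 0.9 /
optimism ≤ 0.02 targets hold from n = 350 onward, so the second
consecutive satisfying assessment — n = 400, about 18 EPP — completes
both rules and its model is the final one (`lc$final_models$rule1`).
Note the stop arrives *after* the 10-EPP size (250) — adaptive monitoring
demands empirical evidence of adequate performance, not just an event
count.

`run_study()` wraps this into repeated without-replacement draws from a
population, summarizing stopping sizes and final-model performance by
median and IQR and comparing bootstrap-corrected against holdout
estimates; `plot()` methods draw the learning curves. A thin command-line
wrapper lives at `inst/cli/adaptsize.R` (subcommands `simulate-data`,
`fixed-size`, `run-adaptive`, `run-study`), with demo run configurations
under `inst/extdata/`.

See the methods vignette (`vignettes/adaptive-sample-size.Rmd`) for the
model, the design decisions, and what the synthetic scenarios do and do
not emulate.

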