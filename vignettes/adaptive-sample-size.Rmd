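---
title: "Adaptive sample size determination for clinical prediction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive sample size determination for clinical prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A clinical prediction model estimates an individual's risk of a binary
outcome (a malignant tumor, obstructive coronary disease) from a set of
prespecified predictors. Developing such a model on too few patients
produces an *overfit* model: its risks are too extreme, and its apparent
performance flatters it. Classical planning tools pick a single sample size
in advance — a target number of events per candidate parameter (EPP), or
the Cox–Snell-R²-based minimum-sample-size criteria — but a fixed number
cannot react to what the accumulating data actually show.

`adaptsize` implements the complementary, *adaptive* approach: monitor the
model's internally validated performance while patients accrue, and stop
recruitment once prespecified performance targets hold. The package
provides the full pipeline: data model, fixed a-priori calculators, four
prespecified modeling strategies, enhanced-bootstrap internal validation,
the adaptive engine itself, synthetic case-study generators, and a
resampling-study harness with holdout checks.

## The adaptive procedure

With a modeling strategy frozen in advance, the procedure is:

1. Compute an initial fixed estimate $N_0$ (`riley_min_n()`), to gauge
   feasibility; it is advisory, not binding (the `min_n` argument of
   `run_adaptive()` can enforce it).
2. Recruit $N_{\text{start}}$ patients (default 100) and fit the strategy,
   obtaining the interim model $M_D$.
3. Internally validate $M_D$ with Harrell's enhanced bootstrap
   (`enhanced_bootstrap()`, default $B = 200$): each replicate resamples
   $n$ rows with replacement, re-runs the *complete* strategy (knot
   re-estimation, re-selection, re-imputation where configured) to get
   $M_B$, and records the performance of $M_B$ on the replicate
   ($PM_B$) and on the original data ($PM_O$). The optimism of a measure
   is $\overline{PM_B - PM_O}$, and the bootstrap-corrected value is the
   apparent performance minus that optimism.
4. Evaluate the stopping rules on the corrected calibration slope and the
   AUC optimism.
5. Recruit $N_{\text{add}}$ more patients (default 50) and repeat.
6. Stop when a rule holds; the model fitted at the assessment that
   *completes* the rule's consecutive requirement is the final model.

Two measures drive the rules because they directly express overfitting:

* the **calibration slope**, the MLE coefficient of the outcome regressed
  on the model's linear predictor — below 1 means risks too extreme;
* the **AUC (c-statistic) optimism**, apparent minus corrected AUC.

The default rules require slope $\ge 0.9$ and optimism $\le 0.02$
(rule 1) or $\le 0.01$ (rule 2) on **two consecutive** assessments.
Thresholds are inclusive; the consecutive requirement damps the noise of
reassessing after every small batch. The calibration intercept is computed
but deliberately not used: at internal validation it carries little
information.

## Modeling strategies

All four strategies are deterministic functions of (data, specification,
seed), built from `strategy_spec()`:

* **Basic**: maximum-likelihood logistic regression on the prespecified
  predictors, continuous terms linear.
* **Restricted cubic splines**: each spline-flagged continuous predictor
  gains one basis column (3 knots), so the ovarian-like candidate set
  grows from 7 to 10 parameters and the CAD-like set from 12 to 16.
  Knots sit at the 0.10/0.50/0.90 empirical quantiles of the *current*
  development data — the convention of the standard spline-regression
  framework — and are stored in the model, so bootstrap models carry
  their own knots and prediction never re-estimates them. Degenerate
  (tied) quantiles fall back to a linear term.
* **Firth's correction**: Jeffreys-prior penalized likelihood
  $\ell(\beta) + \tfrac12 \log\det I(\beta)$, fitted by Newton iterations
  on the hat-value-modified score with step-halving. Estimates are finite
  under complete separation and shrunk relative to MLE; no post-hoc
  intercept correction is applied (it would not affect the slope or the
  AUC, the two monitored measures — real deployments should recalibrate
  the intercept).
* **Backward elimination**: greedy removal of the non-forced predictor
  block with the largest likelihood-ratio p-value $\ge \alpha$ (default
  0.05), refitting after each removal. Categorical dummy blocks and
  spline pairs are tested and removed as whole blocks; ties break in
  schema order, making the procedure reproducible. Forcing key predictors
  (age; age and sex in the CAD-like setting) guarantees a non-empty
  model. Whether block LR tests or single-coefficient Wald tests are used
  is genuinely open in this design space; LR-on-blocks was chosen because
  it treats multi-column predictors coherently, and it is a documented
  package choice.

Numerical settings: MLE fits go through `stats::glm.fit` (IRLS,
convergence as in base R) with an explicit rank check that names collinear
columns; quasi-separation is flagged (`converged = FALSE`) when fitted
probabilities hit machine 0/1 and a coefficient exceeds 10 on the logit
scale, never silently accepted. Firth iterations stop when the relative
change of the penalized likelihood falls below 1e-8 and the step is below
1e-6, with a 250-iteration cap.

## Internal validation details

The apparent calibration slope is *refitted*, not assumed to be 1: for MLE
the score equations force it to 1 on the training data (a property the
test suite asserts to 1e-6), but for Firth models it genuinely differs.
Replicates whose refit fails — a single-class resample, non-convergence,
or an undefined metric — are dropped and counted (`failed_replicates`),
and a warning is raised when fewer than half of the replicates survive;
an assessment whose bootstrap fails entirely is recorded as `undefined`
and **resets** the consecutive counter of every rule. The alternative
(letting a satisfied assessment bridge an undefined one) risks stopping on
unverifiable performance, so the conservative reset is the default and
only behavior.

Randomness is organized as counter-derived substreams: an assessment seed
is derived from the run seed and the assessment index, and replicate $b$
uses a substream of the assessment seed, so results are bit-reproducible
and independent of execution order.

## Missing data

Two policies are provided, mirroring how incomplete development data are
handled in practice:

* `single_fcs`: one stochastic chained-equations imputation
  (`fcs_impute_single()`) of the development data before fitting and
  bootstrapping — the pragmatic, illustrative choice for monitoring.
* `mi_in_bootstrap`: multiple imputation embedded in the bootstrap
  (`mi_in_bootstrap()`): the apparent performance averages measures over
  $m$ imputations, and every replicate re-imputes its resample $m$ times,
  averaging $PM_B$ and $PM_O$ across imputations *before* the optimism
  difference; the replicate model of imputation $j$ is evaluated on the
  $j$-th apparent imputation of the original data. With $m = 1$ this is
  single stochastic imputation inside the bootstrap. The exact
  combination order (average performances versus pool models first) is an
  open design point; averaging performances is this package's documented
  choice, and only performance averaging — not Rubin's-rules pooled
  inference — is needed for monitoring.

The imputation models regress each incomplete column on all other
predictors plus the outcome (linear with a normal error draw, logistic, or
multinomial by column type), for 5 cycles — the default of standard
chained-equations software. Columns with more than 95% missingness are
refused.

## Fixed a-priori calculators

`epp_sample_size(epp, p, phi)` returns $\lceil epp \cdot p / \varphi
\rceil$: with 7 parameters and an event fraction of 1931/5914, 10 EPP
needs 215 patients; with 12 parameters and 2127/4888, 276. The Cox–Snell
criteria (`riley_min_n()`) combine a shrinkage target ($S = 0.9$), a
bound on apparent-R² optimism ($\delta = 0.05$), and a risk-margin
criterion (95% z-value, margin 0.05). The anticipated Cox–Snell R² has
**no default**: it is a planning judgment, supplied by the user (the demo
configurations carry illustrative values with a provenance note).
`round_to_batch()` lifts any fixed size to the next accrual batch, e.g.
314 → 350 and 669 → 700 at batches of 50.

## What the synthetic scenarios emulate — and what they do not

`ovarian_like_scenario()` and `cad_like_scenario()` emulate the *case mix*
of the two worked case studies: predictor marginals (means, ranges,
prevalences, the 0–4 papillation score), target event fractions (0.33 and
0.44), target population AUC of the true linear predictor (0.90 and
0.70), and, for the CAD-like setting, missingness in five predictors at
realistic rates (6.4%, 6.3%, 4.1%, 2%, 13%), missing at random with age
as the driver. The papillation count enters as a single numeric score
0–4 rather than dummy codes — the coding consistent with a 7-parameter
model for 7 predictors — and three-level smoking is reference-coded,
giving 12 parameters for 11 predictors.

Dependence is a Gaussian copula with a packaged correlation matrix
(moderate positive correlation between the two diameter variables, whose
structural bound — solid component never exceeding the lesion — holds for
every generated row because the solid diameter is drawn as a random
fraction of the lesion diameter with a point mass at zero). Continuous
shapes are truncated normals and log-normals chosen for plausibility
(right-skewed diameters, bounded age). These joint-distribution choices
are modeling decisions of this package, not estimates of any real
dataset: passing tests show the machinery behaves correctly under a
realistic case mix, not that any specific clinical dataset would give the
same stopping sample sizes.

Calibration (`calibrate_scenario()`) solves the intercept by monotone
root-finding (mean risk = target event fraction) and the coefficient
scale by 45 bisection steps on the simulated c-statistic, on a fixed-seed
draw of 1e5 patients with shared uniform variates so the objective is
monotone. Standardization constants are frozen at calibration, making the
true raw-scale coefficients (`true_coefficients()`) well defined; a
correctly specified MLE at n = 50,000 recovers them within Monte-Carlo
error, the core validity check for everything downstream.

## The resampling-study harness

`run_repetition()` permutes a fixed population; the first
$N_{\max}$ rows form the accrual stream (sampling without replacement, as
when mimicking real recruitment) and the remainder — e.g. 2914 of 5914,
or 1888 of 4888, at a cap of 3000 — is the holdout, on which every
interim model is also evaluated. `run_study()` repeats this with
independent seed-derived permutations and summarizes stopping sample
sizes, EPP, and corrected performance per rule by median and
interquartile range; quartiles use linear interpolation between order
statistics (type 7), a fixed convention so summaries are bit-exactly
reproducible. Repetitions never met by a rule are censored at the cap and
counted separately. Sampling without replacement within a repetition
understates between-curve variability relative to truly independent
samples; that caveat is inherited by any such design.

Holdout evaluation is a check available only in a resampling study — in a
real prospective application there is a single learning curve and no
holdout.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to exercise every property
at high power while keeping a laptop run comfortable: the study-level
tests use 6–10 repetitions with $B = 100$ and an accrual cap of 1500 on
populations of 5914 and 4888; generator-calibration checks use fresh
draws of 1e5 and coefficient recovery at 50,000; Monte-Carlo properties
(positive mean optimism, shrinking optimism) average over 50 seeds with
$B = 20$. A full-scale evaluation (500 repetitions, $B = 200$, cap 3000)
uses the same code paths and remains configurable.

## Known limitations

* The procedure is monitoring-based: it controls no formal sequential
  error rate, and stopping early on a lucky assessment remains possible —
  the consecutive requirement and the advisory $N_0$ mitigate, not
  eliminate, this.
* Stopping sample sizes depend on the whole modeling context (event
  fraction, predictive strength, strategy); numbers obtained on the
  synthetic scenarios characterize those scenarios, not any particular
  clinical dataset.
* Only binary outcomes and logistic models are supported; survival and
  multinomial outcomes, penalization beyond Firth, interactions, and
  machine-learning estimators are out of scope.
* `single_fcs` understates imputation uncertainty by design; use
  `mi_in_bootstrap` when that matters and budget the computation
  accordingly.
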