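Package: adaptsize
Title: Adaptive Sample Size Determination for Clinical Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequential (adaptive) sample size determination for developing
    clinical risk prediction models with a binary outcome. Development data
    are accrued in batches, each interim model is internally validated with
    Harrell's enhanced bootstrap, and accrual stops once prespecified targets
    on the optimism-corrected calibration slope and c-statistic optimism are
    met on consecutive assessments. Also provides fixed a-priori sample size
    calculators (events-per-parameter and Cox-Snell R-squared based minimum
    sample size criteria), four prespecified modeling strategies (maximum
    likelihood logistic regression, restricted cubic splines, Firth's
    penalized logistic regression, and backward elimination with forced
    predictors), synthetic case-study generators with missing-data support,
    and a resampling-study harness that produces learning curves with
    holdout checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
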