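test_that("restricted cubic spline basis follows the closed form", {
  expect_equal(rcs_basis(1, c(0, 1, 2)), 0.25)        # direct evaluation
  # zero at and below the first knot
  expect_equal(rcs_basis(c(-3, -0.1, 0), c(0, 1, 2)), c(0, 0, 0))
  # linear (zero second difference) beyond the boundary knots
  grid <- seq(2.5, 8, by = 0.25)
  s <- rcs_basis(grid, c(0, 1, 2))
  expect_lt(max(abs(diff(diff(s)))), 1e-9)
  grid_lo <- seq(-5, -0.5, by = 0.25)
  expect_equal(rcs_basis(grid_lo, c(0, 1, 2)), rep(0, length(grid_lo)))
  expect_error(rcs_basis(1, c(0, 1, 1)), "strictly increasing")
  expect_error(rcs_basis(1, c(2, 1, 0)), "strictly increasing")
})

test_that("spline expansion adds one parameter per flagged predictor", {
  meta <- list(predictor_meta("a", "continuous", spline = TRUE),
               predictor_meta("b", "continuous"),
               predictor_meta("c", "continuous", spline = TRUE))
  t <- with_seed(1, patient_table(rbinom(200, 1, 0.4),
                                  data.frame(a = rnorm(200), b = rnorm(200),
                                             c = rnorm(200)), meta))
  m0 <- fit_strategy(t, strategy_spec("mle"))
  m1 <- fit_strategy(t, strategy_spec("mle", use_splines = TRUE))
  expect_equal(m0$n_params, 3L)
  expect_equal(m1$n_params, 5L)
  # stored knots are the development-data quantiles
  expect_equal(m1$recipe$a$knots,
               unname(quantile(t$X$a, c(0.1, 0.5, 0.9), type = 7)))
})

test_that("MLE logistic regression matches closed forms and brute force", {
  # intercept-only: logit of the event fraction
  t0 <- patient_table(rep(c(1, 0), c(3, 7)), data.frame(row.names = 1:10),
                      list())
  expect_equal(fit_mle_logistic(t0)$intercept, qlogis(0.3), tolerance = 1e-7)
  # single binary predictor: the log odds ratio
  t1 <- patient_table(c(rep(1, 10), rep(0, 30), rep(1, 20), rep(0, 20)),
                      data.frame(x = rep(c(0, 1), c(40, 40))),
                      list(predictor_meta("x", "binary")))
  expect_equal(unname(fit_mle_logistic(t1)$coefficients["x"]), log(3),
               tolerance = 1e-7)
  # brute-force likelihood maximization agrees to 1e-6 on a 3-parameter toy
  t2 <- toy_table(120, seed = 11)
  m <- fit_mle_logistic(t2)
  Xd <- cbind(1, as.matrix(t2$X))
  nll <- function(b) -sum(t2$y * (Xd %*% b) -
                            adaptsize:::log1pexp(drop(Xd %*% b)))
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(c(m$intercept, m$coefficients)), unname(opt$par),
               tolerance = 1e-6)
})

test_that("separation is flagged, never silent", {
  t <- patient_table(c(0, 0, 0, 1, 1, 1),
                     data.frame(x = c(-3, -2, -1, 1, 2, 3)),
                     list(predictor_meta("x", "continuous")))
  m <- fit_mle_logistic(t)
  expect_false(m$converged)
  expect_true(m$separated)
})

test_that("rank deficiency errors name the collinear columns", {
  t <- toy_table(50, seed = 2)
  t$X$x2 <- 2 * t$X$x1
  expect_error(fit_mle_logistic(t), "rank deficient.*x2")
})

test_that("Firth fits are finite under separation and shrink toward zero", {
  t <- patient_table(c(0, 0, 0, 1, 1, 1),
                     data.frame(x = c(-3, -2, -1, 1, 2, 3)),
                     list(predictor_meta("x", "continuous")))
  mf <- fit_firth_logistic(t)
  expect_true(mf$converged)
  expect_true(all(is.finite(c(mf$intercept, mf$coefficients))))
  mle <- fit_mle_logistic(t)  # diverged fit, coefficients huge
  expect_lt(abs(mf$coefficients["x"]), abs(mle$coefficients["x"]))
})

test_that("Firth reduces to the (k+1/2)/(n+1) rule for intercept-only", {
  for (kn in list(c(3, 10), c(1, 7), c(12, 40))) {
    t <- patient_table(rep(c(1, 0), c(kn[1], kn[2] - kn[1])),
                       data.frame(row.names = seq_len(kn[2])), list())
    expect_equal(fit_firth_logistic(t)$intercept,
                 qlogis((kn[1] + 0.5) / (kn[2] + 1)), tolerance = 1e-5)
  }
})

test_that("Firth and MLE agree at large n", {
  t <- toy_table(50000, seed = 21)
  mf <- fit_firth_logistic(t)
  ml <- fit_mle_logistic(t)
  expect_equal(c(mf$intercept, mf$coefficients),
               c(ml$intercept, ml$coefficients), tolerance = 5e-3)
})

test_that("backward elimination drops null predictors, keeps forced and strong", {
  # x1 strong, x2 true null, x3 forced null
  t <- with_seed(77, {
    X <- data.frame(x1 = rnorm(500), x2 = rnorm(500), x3 = rnorm(500))
    y <- rbinom(500, 1, plogis(-0.3 + 1.2 * X$x1))
    patient_table(y, X, lapply(names(X), predictor_meta, type = "continuous"))
  })
  spec <- strategy_spec("mle", selection = "backward", forced = "x3")
  m <- backward_eliminate(t, spec)
  expect_true(all(c("x1", "x3") %in% m$selected))
  expect_false("x2" %in% m$selected)

  # hand-rolled elimination loop as oracle: drop largest-p block, refit
  oracle_sel <- names(t$X)
  repeat {
    full <- glm(reformulate(oracle_sel, "y"),
                data = cbind(y = t$y, t$X), family = binomial)
    cand <- setdiff(oracle_sel, "x3")
    if (!length(cand)) break
    pv <- vapply(cand, function(nm) {
      red <- glm(reformulate(setdiff(oracle_sel, nm), "y"),
                 data = cbind(y = t$y, t$X), family = binomial)
      pchisq(red$deviance - full$deviance, 1, lower.tail = FALSE)
    }, numeric(1))
    if (max(pv) < 0.05) break
    oracle_sel <- setdiff(oracle_sel, cand[which.max(pv)])
  }
  expect_setequal(m$selected, oracle_sel)
})

test_that("backward elimination boundary behavior", {
  t <- toy_table(200, seed = 3)
  # all predictors forced: identical to the plain fit
  spec_all <- strategy_spec("mle", selection = "backward",
                            forced = names(t$X))
  plain <- fit_mle_logistic(t)
  m <- backward_eliminate(t, spec_all)
  expect_equal(m$coefficients, plain$coefficients)
  # alpha = 1: removal requires p >= 1, so no predictor is removed
  spec_keep <- strategy_spec("mle", selection = "backward", alpha = 1)
  m2 <- backward_eliminate(t, spec_keep)
  expect_setequal(m2$selected, names(t$X))
})

test_that("categorical blocks are eliminated as a whole", {
  t <- with_seed(9, {
    g <- sample(c("a", "b", "c"), 400, replace = TRUE)
    X <- data.frame(x = rnorm(400), g = g, stringsAsFactors = FALSE)
    y <- rbinom(400, 1, plogis(1.0 * X$x))       # g is pure noise
    patient_table(y, X, list(predictor_meta("x", "continuous"),
                             predictor_meta("g", "categorical",
                                            levels = c("a", "b", "c"))))
  })
  spec <- strategy_spec("mle", selection = "backward", forced = "x")
  m <- backward_eliminate(t, spec)
  expect_false("g" %in% m$selected)
  expect_false(any(grepl("^g\\.", names(m$coefficients))))
})

test_that("prediction reuses stored knots and rejects unseen levels", {
  meta <- list(predictor_meta("a", "continuous", spline = TRUE),
               predictor_meta("g", "categorical", levels = c("a", "b", "c")))
  t <- with_seed(13, patient_table(
    rbinom(300, 1, 0.4),
    data.frame(a = rnorm(300), g = sample(c("a", "b", "c"), 300, TRUE),
               stringsAsFactors = FALSE), meta))
  m <- fit_strategy(t, strategy_spec("mle", use_splines = TRUE))
  # beyond-knot extrapolation stays finite (linear continuation)
  nd <- data.frame(a = c(-50, 50), g = c("a", "b"))
  expect_true(all(is.finite(predict_lp(m, nd))))
  expect_error(predict_lp(m, data.frame(a = 1, g = "z")), "unseen level")
  # strategy application is deterministic
  m2 <- fit_strategy(t, strategy_spec("mle", use_splines = TRUE))
  expect_identical(m$coefficients, m2$coefficients)
})

test_that("all-zero coefficients give a constant linear predictor", {
  t <- toy_table(30, seed = 4)
  m <- fit_mle_logistic(t)
  m$coefficients[] <- 0
  expect_equal(predict_lp(m, t), rep(m$intercept, t$n))
})

test_that("fitted models serialize to JSON and back", {
  t <- toy_table(100, seed = 6)
  m <- fit_mle_logistic(t)
  js <- jsonlite::fromJSON(model_to_json(m))
  expect_equal(js$intercept, m$intercept)
  expect_equal(unlist(js$coefficients), m$coefficients)
})
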