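test_that("c-statistic equals pairwise enumeration with half-ties", {
  # worked example: events {0.9, 0.4} vs non-events {0.5, 0.2, 0.4}
  expect_equal(c_statistic(c(0.9, 0.4, 0.5, 0.2, 0.4), c(1, 1, 0, 0, 0)),
               4.5 / 6)
  expect_equal(c_statistic(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)   # perfect
  expect_equal(c_statistic(rep(2, 6), c(1, 0, 1, 0, 0, 1)), 0.5)  # all ties
  # random score vectors against brute force and an independent library
  for (s in 1:5) {
    with_seed(s, {
      y <- rbinom(20, 1, 0.4)
      if (sum(y) %in% c(0, 20)) y[1:2] <- c(0, 1)
      sc <- round(rnorm(20), 1)  # rounding forces ties
      expect_equal(c_statistic(sc, y), auc_enum(sc, y))
      expect_equal(c_statistic(sc, y),
                   as.numeric(pROC::auc(y, sc, quiet = TRUE,
                                        direction = "<")))
    })
  }
  # invariant under strictly increasing transforms
  sc <- c(0.1, 0.7, 0.3, 0.9, 0.5, 0.2)
  y <- c(0, 1, 0, 1, 1, 0)
  expect_equal(c_statistic(exp(3 * sc), y), c_statistic(sc, y))
  expect_error(c_statistic(c(1, 2), c(1, 1)), "both outcome classes")
})

test_that("calibration slope has the MLE training-data and scaling properties", {
  t <- toy_table(300, seed = 8)
  m <- fit_mle_logistic(t)
  lp <- predict_lp(m, t)
  # apparent slope of an MLE fit on its own data is exactly 1
  expect_equal(as.numeric(calibration_slope(lp, t$y)), 1, tolerance = 1e-6)
  # halving the linear predictor doubles the slope
  s1 <- as.numeric(calibration_slope(lp, t$y))
  s2 <- as.numeric(calibration_slope(lp / 2, t$y))
  expect_equal(s2, 2 * s1, tolerance = 1e-6)
  expect_error(calibration_slope(rep(1.3, t$n), t$y), "zero-variance")
})

test_that("overfit models show slope below 1 on holdout", {
  # 7 parameters fit on 100 patients, evaluated on a large holdout
  slopes <- vapply(1:5, function(s) {
    t <- toy_table(10100, seed = 100 + s,
                   beta = c(0.5, -0.4, 0.3, 0.2, -0.2, 0.15, 0.1))
    m <- fit_mle_logistic(t[1:100])
    as.numeric(calibration_slope(predict_lp(m, t[101:10100]),
                                 t$y[101:10100]))
  }, numeric(1))
  expect_lt(mean(slopes), 1)
})

test_that("a data-independent model has no optimism in expectation", {
  # A frozen model cannot overfit: PM_B and PM_O differ only through which
  # rows the fixed model is evaluated on, so the mean optimism is zero up
  # to Monte-Carlo noise, and corrected equals apparent up to the same.
  t <- toy_table(400, seed = 14)
  frozen <- fit_mle_logistic(t)
  fit_const <- function(ti, s) frozen
  pe <- adaptsize:::boot_engine(t, B = 300, seed = 5, fit_fn = fit_const,
                                eval_fn = adaptsize:::eval_perf)
  expect_equal(pe$auc_optimism, 0, tolerance = 0.005)
  expect_equal(pe$slope_optimism, 0, tolerance = 0.03)
  # the corrected = apparent - optimism identity is exact
  expect_equal(pe$auc_corrected, pe$auc_apparent - pe$auc_optimism)
  expect_equal(pe$slope_corrected, pe$slope_apparent - pe$slope_optimism)
})

test_that("enhanced bootstrap equals a hand-rolled replicate loop", {
  t <- toy_table(30, seed = 16)
  spec <- strategy_spec("mle")
  B <- 3
  seed <- 3  # all three replicate refits converge on this substream
  pe <- enhanced_bootstrap(t, spec, B = B, seed = seed)

  # oracle: explicit loop with glm fits and enumeration AUC
  df <- cbind(y = t$y, t$X)
  fit_glm <- function(d) glm(y ~ x1 + x2, data = d, family = binomial)
  perf <- function(fit, d) {
    lp <- predict(fit, newdata = d)
    cal <- glm(d$y ~ lp, family = binomial)
    c(auc_enum(lp, d$y), unname(coef(cal)[2]))
  }
  mD <- fit_glm(df)
  app <- perf(mD, df)
  opt <- matrix(NA_real_, B, 2)
  for (b in 1:B) {
    idx <- with_seed(mix_seed(seed, b), sample.int(30, 30, replace = TRUE))
    db <- df[idx, ]
    mB <- fit_glm(db)
    opt[b, ] <- perf(mB, db) - perf(mB, df)
  }
  expect_equal(pe$B_used, 3L)
  expect_equal(pe$auc_apparent, app[1], tolerance = 1e-10)
  expect_equal(pe$slope_apparent, app[2], tolerance = 1e-8)
  expect_equal(pe$auc_optimism, mean(opt[, 1]), tolerance = 1e-10)
  expect_equal(pe$slope_optimism, mean(opt[, 2]), tolerance = 1e-8)
  expect_equal(pe$auc_corrected, pe$auc_apparent - pe$auc_optimism)
})

test_that("bootstrap estimates are deterministic in (data, spec, B, seed)", {
  t <- tiny_population(n = 150, seed = 31)
  spec <- strategy_spec("mle")
  a <- enhanced_bootstrap(t, spec, B = 25, seed = 99)
  b <- enhanced_bootstrap(t, spec, B = 25, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- enhanced_bootstrap(t, spec, B = 25, seed = 100)
  expect_false(identical(a$auc_optimism, c$auc_optimism))
})

test_that("optimism is positive in expectation and shrinks with n", {
  cfg <- tiny_scenario()
  spec <- strategy_spec("mle")
  opt_small <- numeric(50)
  opt_large <- numeric(50)
  for (s in 1:50) {
    pop <- generate_population(cfg, n = 2000, seed = 4000 + s)
    opt_small[s] <- enhanced_bootstrap(pop[1:100], spec, B = 20,
                                       seed = s)$auc_optimism
    opt_large[s] <- enhanced_bootstrap(pop, spec, B = 20,
                                       seed = s)$auc_optimism
  }
  expect_gt(mean(opt_small), 0)
  expect_gt(mean(opt_large), 0)
  expect_lt(mean(opt_large), mean(opt_small))
})

test_that("corrected performance approaches the population truth at large n", {
  cfg <- tiny_scenario()
  pop <- generate_population(cfg, n = 3000, seed = 555)
  pe <- enhanced_bootstrap(pop, strategy_spec("mle"), B = 50, seed = 3)
  expect_equal(pe$slope_corrected, 1, tolerance = 0.05)
  expect_equal(pe$auc_corrected, cfg$target_auc, tolerance = 0.02)
  expect_equal(pe$auc_optimism, 0, tolerance = 0.01)
})

test_that("failed replicates are dropped and counted", {
  t <- toy_table(40, seed = 18)
  flaky <- local({
    calls <- 0
    function(ti, s) {
      calls <<- calls + 1
      if (calls %% 2 == 0) stop("boom")
      fit_mle_logistic(ti)
    }
  })
  pe <- adaptsize:::boot_engine(t, B = 6, seed = 2, fit_fn = flaky,
                                eval_fn = adaptsize:::eval_perf)
  expect_equal(pe$B_used + pe$failed_replicates, 6L)
  expect_gt(pe$failed_replicates, 0L)
  fail_after_first <- local({
    calls <- 0
    function(ti, s) {
      calls <<- calls + 1
      if (calls > 1) stop("boom")
      fit_mle_logistic(ti)
    }
  })
  expect_error(adaptsize:::boot_engine(t, B = 3, seed = 2,
                                       fit_fn = fail_after_first,
                                       eval_fn = adaptsize:::eval_perf),
               "all 3 replicates failed")
})
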