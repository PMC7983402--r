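# Shared fixtures: all data are generated in code at test time.

mix_seed <- adaptsize:::mix_seed
with_seed <- adaptsize:::with_seed

# Small logistic toy table: p standard-normal predictors, known coefficients.
toy_table <- function(n, seed = 1, beta = c(1, -0.5), intercept = -0.5) {
  p <- length(beta)
  with_seed(seed, {
    X <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(X) <- paste0("x", seq_len(p))
    y <- rbinom(n, 1, plogis(intercept + as.matrix(X) %*% beta))
    meta <- lapply(names(X), predictor_meta, type = "continuous")
    patient_table(y, X, meta)
  })
}

# Brute-force pairwise c-statistic (ties counted 1/2); the enumeration
# oracle for the rank-based implementation.
auc_enum <- function(scores, y) {
  s1 <- scores[y == 1]
  s0 <- scores[y == 0]
  wins <- 0
  for (a in s1) for (b in s0) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(s1) * length(s0))
}

# Calibrated packaged scenarios are expensive; compute once per test run.
.fixture_cache <- new.env(parent = emptyenv())

calibrated_ovarian <- function() {
  if (is.null(.fixture_cache$ov))
    .fixture_cache$ov <- calibrate_scenario(ovarian_like_scenario())
  .fixture_cache$ov
}

calibrated_cad <- function() {
  if (is.null(.fixture_cache$cad))
    .fixture_cache$cad <- calibrate_scenario(cad_like_scenario())
  .fixture_cache$cad
}

# A deliberately small, fast scenario for engine-level tests: two continuous
# and one binary predictor, moderate signal.
tiny_scenario <- function(seed = 42L) {
  if (!is.null(.fixture_cache$tiny)) return(.fixture_cache$tiny)
  meta <- list(predictor_meta("a", "continuous"),
               predictor_meta("b", "continuous"),
               predictor_meta("c", "binary"))
  marg <- list(a = list(dist = "truncnorm", mean = 0, sd = 1,
                        lower = -5, upper = 5),
               b = list(dist = "truncnorm", mean = 10, sd = 2,
                        lower = 0, upper = 20),
               c = list(dist = "bernoulli", p = 0.3))
  corr <- diag(3)
  corr[1, 2] <- corr[2, 1] <- 0.3
  dimnames(corr) <- list(names(marg), names(marg))
  cfg <- adaptsize:::scenario_config("tiny", meta, marg, corr,
                                     beta = c(a = 1, b = -0.6, c = 0.8),
                                     target_phi = 0.35, target_auc = 0.80,
                                     pop_size = 2000L, seed = seed)
  .fixture_cache$tiny <- calibrate_scenario(cfg, n_calib = 2e4)
  .fixture_cache$tiny
}

tiny_population <- function(n = 2000L, seed = 7L) {
  generate_population(tiny_scenario(), n = n, seed = seed)
}
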