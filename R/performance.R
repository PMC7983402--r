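#' Concordance statistic (AUC)
#'
#' Probability that a randomly chosen event receives a higher score than a
#' randomly chosen non-event, with ties counted 1/2 (the Mann-Whitney
#' convention, computed from midranks). Invariant under any strictly
#' increasing transform of the scores.
#'
#' @param scores Numeric risk scores or linear predictors.
#' @param y Binary outcome vector (1 = event).
#' @return Value in `[0, 1]`.
#' @export
c_statistic <- function(scores, y) {
  stopifnot(length(scores) == length(y))
  if (anyNA(scores) || anyNA(y)) stop("missing values in scores or outcome")
  n1 <- as.numeric(sum(y == 1))
  n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0)
    stop("c-statistic undefined: both outcome classes are required")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration slope of a linear predictor
#'
#' Slope coefficient from the maximum-likelihood logistic regression of the
#' observed outcome on the linear predictor (with free intercept). A slope
#' below 1 indicates risk estimates that are too extreme (overfitting); above
#' 1, too modest. For a model fitted by MLE and evaluated on its own training
#' data the slope is exactly 1 (score equations).
#'
#' @param lp Linear predictor vector (must have nonzero variance).
#' @param y Binary outcome vector.
#' @return Slope (numeric scalar) with attribute `"converged"`; separation in
#'   the 2-parameter calibration fit is flagged through that attribute.
#' @export
calibration_slope <- function(lp, y) {
  stopifnot(length(lp) == length(y))
  if (anyNA(lp)) stop("missing values in linear predictor")
  if (sum(y == 1) == 0L || sum(y == 0) == 0L)
    stop("calibration slope undefined: both outcome classes are required")
  if (stats::var(lp) < 1e-12)
    stop("calibration slope undefined: zero-variance linear predictor")
  fit <- mle_core(matrix(lp, ncol = 1L, dimnames = list(NULL, "lp")), y)
  slope <- unname(fit$coef["lp"])
  attr(slope, "converged") <- fit$converged
  slope
}

# Calibration intercept (intercept of y ~ offset(lp)); computed for
# completeness, not used by the stopping rules.
calibration_intercept <- function(lp, y) {
  fit <- suppressWarnings(
    stats::glm.fit(matrix(1, length(y)), y, offset = lp,
                   family = stats::binomial()))
  unname(fit$coefficients[1L])
}

# Evaluate a fitted model on a table: c(auc, slope). Errors propagate.
eval_perf <- function(model, t) {
  lp <- predict_lp(model, t)
  c(auc = c_statistic(lp, t$y), slope = as.numeric(calibration_slope(lp, t$y)))
}

# Generic enhanced-bootstrap engine. fit_fn(table, seed) -> model;
# eval_fn(model, table) -> c(auc, slope). Replicates whose resample has a
# single class, whose refit fails or does not converge, or whose metric is
# undefined are dropped and counted. Exposed internally so tests can inject
# degenerate fitters.
boot_engine <- function(t, B, seed, fit_fn, eval_fn) {
  stopifnot(B >= 1L)
  mD <- fit_fn(t, mix_seed(seed, 0L))
  app <- eval_fn(mD, t)
  opt <- matrix(NA_real_, nrow = B, ncol = 2L)
  failed <- 0L
  for (b in seq_len(B)) {
    res <- tryCatch({
      idx <- with_seed(mix_seed(seed, b), sample.int(t$n, t$n, replace = TRUE))
      tb <- t[idx]
      if (sum(tb$y) == 0L || sum(tb$y) == tb$n) stop("single-class resample")
      mB <- fit_fn(tb, mix_seed(seed, 100000L + b))
      if (isFALSE(mB$converged)) stop("bootstrap refit did not converge")
      eval_fn(mB, tb) - eval_fn(mB, t)
    }, error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else opt[b, ] <- res
  }
  if (failed == B)
    stop("enhanced bootstrap failed: all ", B, " replicates failed")
  optimism <- colMeans(opt, na.rm = TRUE)
  perf_estimate(t, app, optimism, B, failed, mD,
                intercept_apparent = tryCatch(
                  calibration_intercept(predict_lp(mD, t), t$y),
                  error = function(e) NA_real_))
}

perf_estimate <- function(t, app, optimism, B, failed, model,
                          intercept_apparent = NA_real_) {
  structure(list(
    n = t$n, events = sum(t$y),
    auc_apparent = unname(app["auc"]),
    auc_optimism = unname(optimism[1L]),
    auc_corrected = unname(app["auc"] - optimism[1L]),
    slope_apparent = unname(app["slope"]),
    slope_optimism = unname(optimism[2L]),
    slope_corrected = unname(app["slope"] - optimism[2L]),
    intercept_apparent = intercept_apparent,
    B_requested = as.integer(B),
    B_used = as.integer(B - failed),
    failed_replicates = as.integer(failed),
    low_B = (B - failed) < 0.5 * B,
    model = model), class = "perf_estimate")
}

#' Harrell's enhanced bootstrap internal validation
#'
#' Estimates optimism-corrected performance of a complete modeling strategy.
#' For each of `B` replicates: draw `n` rows with replacement, re-run the
#' entire strategy (spline knot re-estimation, re-selection and — for the
#' `mi_in_bootstrap` policy — re-imputation) to obtain the bootstrap model
#' M_B, record its performance on the replicate (PM_B) and on the original
#' data (PM_O). The optimism of each measure is `mean(PM_B - PM_O)` over
#' usable replicates, and corrected performance is apparent performance of
#' M_D minus the optimism. The apparent calibration slope is refitted, not
#' assumed 1, so penalized estimators are handled correctly.
#'
#' With `imputation = "single_fcs"` and incomplete data, the development
#' data are imputed once (stochastically, seeded) and the bootstrap runs on
#' the completed table; with `"mi_in_bootstrap"` the multiple-imputation
#' nesting of [mi_in_bootstrap()] is used.
#'
#' @param t A [patient_table()].
#' @param spec A [strategy_spec()].
#' @param B Number of bootstrap replicates.
#' @param seed Integer root seed for this assessment; replicate `b` draws
#'   from a counter-derived substream, so results are independent of
#'   execution order.
#' @return An object of class `perf_estimate` with fields `auc_apparent`,
#'   `auc_optimism`, `auc_corrected`, `slope_apparent`, `slope_corrected`,
#'   `n`, `events`, `B_requested`, `B_used`, `failed_replicates`, and the
#'   fitted model `model` (M_D).
#' @export
enhanced_bootstrap <- function(t, spec, B = 200L, seed = 1L) {
  stopifnot(inherits(t, "patient_table"), inherits(spec, "strategy_spec"))
  incomplete <- anyNA(as.data.frame(t$X))
  if (incomplete && spec$imputation == "mi_in_bootstrap")
    return(mi_in_bootstrap(t, spec, B = B, m = spec$m, seed = seed))
  if (incomplete && spec$imputation == "single_fcs")
    t <- fcs_impute_single(t, seed = mix_seed(seed, 17L))
  if (incomplete && spec$imputation == "none")
    stop("incomplete data require an imputation policy")
  spec_c <- spec
  spec_c$imputation <- "none"
  out <- boot_engine(t, B, seed,
                     fit_fn = function(ti, s) fit_strategy(ti, spec_c, s),
                     eval_fn = eval_perf)
  if (out$low_B)
    warning("more than half of the bootstrap replicates failed (B_used = ",
            out$B_used, " of ", out$B_requested, ")")
  out
}

#' @export
print.perf_estimate <- function(x, ...) {
  cat(sprintf("perf_estimate: n = %d, events = %d, B = %d/%d\n",
              x$n, x$events, x$B_used, x$B_requested))
  cat(sprintf("  AUC   apparent %.4f  corrected %.4f  optimism %.4f\n",
              x$auc_apparent, x$auc_corrected, x$auc_optimism))
  cat(sprintf("  slope apparent %.4f  corrected %.4f\n",
              x$slope_apparent, x$slope_corrected))
  invisible(x)
}

#' One-row data frame view of a performance estimate
#'
#' @param x A `perf_estimate`.
#' @param ... Unused.
#' @return A one-row `data.frame` with all scalar fields.
#' @export
as.data.frame.perf_estimate <- function(x, ...) {
  data.frame(n = x$n, events = x$events,
             auc_apparent = x$auc_apparent, auc_corrected = x$auc_corrected,
             auc_optimism = x$auc_optimism,
             slope_apparent = x$slope_apparent,
             slope_corrected = x$slope_corrected,
             intercept_apparent = x$intercept_apparent,
             B_requested = x$B_requested, B_used = x$B_used,
             failed_replicates = x$failed_replicates)
}
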