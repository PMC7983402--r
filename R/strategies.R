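#' Specify a prespecified modeling strategy
#'
#' A strategy is the complete, frozen recipe that turns a development dataset
#' into a fitted logistic prediction model: estimator, spline expansion,
#' variable selection, forced predictors, and missing-data policy. The
#' adaptive procedure and the enhanced bootstrap both re-run the *entire*
#' strategy, so everything data-driven (spline knots, selection, imputation)
#' must live here.
#'
#' @param estimator `"mle"` (maximum likelihood) or `"firth"` (Jeffreys-prior
#'   penalized likelihood; finite estimates under separation, no post-hoc
#'   intercept correction).
#' @param use_splines Expand spline-flagged continuous predictors with a
#'   3-knot restricted cubic spline (one extra parameter per predictor).
#' @param selection `"none"` or `"backward"` (greedy block-wise backward
#'   elimination by likelihood-ratio tests at `alpha`).
#' @param alpha Elimination threshold; a block is removed while its p-value
#'   is `>= alpha`.
#' @param forced Predictor names that can never be eliminated.
#' @param imputation `"none"`, `"single_fcs"` (one stochastic
#'   chained-equations imputation of the development data before fitting and
#'   bootstrapping), or `"mi_in_bootstrap"` (m imputations nested inside
#'   every bootstrap replicate; see [mi_in_bootstrap()]).
#' @param m Number of imputations for `"mi_in_bootstrap"`.
#' @return An object of class `strategy_spec`. The number of spline knots is
#'   fixed at 3.
#' @export
strategy_spec <- function(estimator = c("mle", "firth"), use_splines = FALSE,
                          selection = c("none", "backward"), alpha = 0.05,
                          forced = character(),
                          imputation = c("none", "single_fcs", "mi_in_bootstrap"),
                          m = 5L) {
  estimator <- match.arg(estimator)
  selection <- match.arg(selection)
  imputation <- match.arg(imputation)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1,
            m >= 1L)
  structure(list(estimator = estimator, use_splines = isTRUE(use_splines),
                 spline_knots = 3L, selection = selection, alpha = alpha,
                 forced = as.character(forced), imputation = imputation,
                 m = as.integer(m)),
            class = "strategy_spec")
}

#' Restricted cubic spline basis column (3 knots)
#'
#' With three knots t1 < t2 < t3 the restricted cubic spline adds a single
#' basis column
#' \deqn{s(x) = \frac{(x-t_1)_+^3 - (x-t_2)_+^3 (t_3-t_1)/(t_3-t_2) +
#'   (x-t_3)_+^3 (t_2-t_1)/(t_3-t_2)}{(t_3-t_1)^2}}
#' so the expanded predictor contributes two design columns (x and s(x)).
#' s is identically 0 for x <= t1 and linear for x >= t3 (restricted =
#' linear beyond the boundary knots).
#'
#' @param x Numeric vector.
#' @param knots Three strictly increasing knot locations.
#' @return Numeric vector `s(x)` of the same length as `x`.
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) != 3L || any(!is.finite(knots)) || any(diff(knots) <= 0))
    stop("knots must be 3 strictly increasing finite values")
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  pp3 <- function(u) pmax(u, 0)^3
  (pp3(x - t1) - pp3(x - t2) * (t3 - t1) / (t3 - t2) +
     pp3(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
}

# Design recipe: per-predictor expansion rule with everything data-driven
# (knot locations) frozen in, so bootstrap models carry their own knots and
# prediction never re-estimates anything.
make_recipe <- function(t, spec) {
  recipe <- lapply(t$meta, function(m) {
    kind <- switch(m$type, continuous = "identity", binary = "identity",
                   categorical = "dummy")
    knots <- NULL
    note <- NULL
    if (spec$use_splines && m$spline) {
      x <- t$X[[m$name]]
      knots <- unname(stats::quantile(x, c(0.10, 0.50, 0.90),
                                      na.rm = TRUE, type = 7))
      if (any(diff(knots) <= 0)) {
        # degenerate quantiles (ties): fall back to a linear term
        knots <- NULL
        note <- "degenerate knots; identity expansion used"
      } else {
        kind <- "spline"
      }
    }
    cols <- switch(kind,
      identity = m$name,
      spline   = c(m$name, paste0(m$name, "'")),
      dummy    = paste(m$name, m$levels[-1L], sep = "."))
    list(name = m$name, type = m$type, kind = kind, knots = knots,
         levels = m$levels, cols = cols, note = note)
  })
  names(recipe) <- meta_names(t$meta)
  recipe
}

# Expand raw predictor columns into the numeric design matrix of a recipe.
build_design <- function(recipe, X) {
  if (!length(recipe))
    return(matrix(numeric(0), nrow = nrow(as.data.frame(X)), ncol = 0L))
  cols <- vector("list", 0L)
  for (r in recipe) {
    x <- X[[r$name]]
    if (is.null(x)) stop("column '", r$name, "' absent from data")
    if (r$kind == "dummy") {
      x <- as.character(x)
      bad <- setdiff(unique(x[!is.na(x)]), r$levels)
      if (length(bad))
        stop("unseen level(s) in '", r$name, "': ", paste(bad, collapse = ", "))
      for (j in seq_along(r$levels)[-1L]) {
        v <- as.numeric(x == r$levels[j])
        v[is.na(x)] <- NA_real_
        cols[[r$cols[j - 1L]]] <- v
      }
    } else {
      x <- as.numeric(x)
      cols[[r$cols[1L]]] <- x
      if (r$kind == "spline") cols[[r$cols[2L]]] <- rcs_basis(x, r$knots)
    }
  }
  do.call(cbind, cols)
}

# Number of candidate design parameters (excluding intercept) a strategy
# considers for a schema; the denominator of EPP.
candidate_params <- function(meta, spec) {
  sum(vapply(meta, function(m) {
    if (m$type == "categorical") return(length(m$levels) - 1L)
    1L + as.integer(spec$use_splines && m$spline)
  }, integer(1)))
}

# --- estimator cores ------------------------------------------------------

mle_core <- function(Xd, y) {
  Xd1 <- cbind(`(Intercept)` = rep(1, length(y)), Xd)
  qrX <- qr(Xd1)
  if (qrX$rank < ncol(Xd1)) {
    alias <- colnames(Xd1)[qrX$pivot[(qrX$rank + 1L):ncol(Xd1)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(alias, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm.fit(Xd1, y, family = stats::binomial()))
  mu <- fit$fitted.values
  eps <- 1e-8
  separated <- (any(mu < eps) || any(mu > 1 - eps)) &&
    max(abs(fit$coefficients)) > 10
  list(coef = fit$coefficients, loglik = -fit$deviance / 2,
       converged = isTRUE(fit$converged) && !separated, separated = separated)
}

# Firth-penalized logistic regression: maximizes l(beta) + 0.5 log det I(beta)
# via the hat-value-modified score sum_i (y_i - pi_i + h_i (1/2 - pi_i)) x_i,
# with step-halving whenever the penalized likelihood would decrease.
firth_core <- function(Xd, y, max_iter = 250L, tol = 1e-8) {
  Xd1 <- cbind(`(Intercept)` = rep(1, length(y)), Xd)
  p <- ncol(Xd1)
  qrX <- qr(Xd1)
  if (qrX$rank < p) {
    alias <- colnames(Xd1)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(alias, collapse = ", "))
  }
  pen_ll <- function(beta) {
    eta <- drop(Xd1 %*% beta)
    pi <- expit(eta)
    w <- pmax(pi * (1 - pi), 1e-12)
    I <- crossprod(Xd1, Xd1 * w)
    ld <- determinant(I, logarithm = TRUE)$modulus
    sum(y * eta - log1pexp(eta)) + 0.5 * as.numeric(ld)
  }
  beta <- numeric(p)
  ll_old <- pen_ll(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd1 %*% beta)
    pi <- expit(eta)
    w <- pmax(pi * (1 - pi), 1e-12)
    I <- crossprod(Xd1, Xd1 * w)
    Iinv <- tryCatch(chol2inv(chol(I)), error = function(e) solve(I))
    h <- rowSums((Xd1 %*% Iinv) * Xd1) * w
    U <- drop(crossprod(Xd1, y - pi + h * (0.5 - pi)))
    delta <- drop(Iinv %*% U)
    step <- 1
    ll_new <- -Inf
    repeat {
      cand <- beta + step * delta
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      step <- step / 2
      if (step < 1e-8) { cand <- beta; ll_new <- ll_old; break }
    }
    done <- abs(ll_new - ll_old) < tol * (abs(ll_old) + tol) &&
      max(abs(step * delta)) < 1e-6
    beta <- cand
    ll_old <- ll_new
    if (done) { converged <- TRUE; break }
  }
  list(coef = stats::setNames(beta, colnames(Xd1)), loglik = ll_old,
       converged = converged, separated = FALSE)
}

# --- fitting --------------------------------------------------------------

fit_with_recipe <- function(t, spec, recipe) {
  Xd <- build_design(recipe, t$X)
  if (anyNA(Xd))
    stop("design matrix contains missing values; choose an imputation policy")
  if (sum(t$y) < 1 || sum(1 - t$y) < 1)
    stop("both outcome classes are required for fitting")
  core <- if (spec$estimator == "firth") firth_core(Xd, t$y) else mle_core(Xd, t$y)
  cf <- core$coef
  structure(list(
    intercept = unname(cf[1L]),
    coefficients = cf[-1L],
    recipe = recipe,
    selected = names(recipe),
    converged = core$converged,
    separated = isTRUE(core$separated),
    loglik = core$loglik,
    n_params = length(cf) - 1L,
    estimator = spec$estimator,
    n = t$n, events = sum(t$y),
    spec = spec), class = "fitted_strategy")
}

#' Apply a complete modeling strategy to a development dataset
#'
#' Runs every prespecified step of a [strategy_spec()] — imputation (when
#' configured and the data are incomplete), spline knot estimation, model
#' fitting, and backward elimination — and returns the resulting model M_D.
#' This is the single entry point the adaptive engine and the enhanced
#' bootstrap call, so bootstrap replicates repeat all data-driven steps.
#'
#' @param t A [patient_table()].
#' @param spec A [strategy_spec()].
#' @param seed Integer seed for the stochastic imputation draw (only used
#'   when imputation runs).
#' @return An object of class `fitted_strategy`: `intercept`,
#'   `coefficients` (named, over the expanded design), `recipe` (stored
#'   expansion incl. knot locations), `selected` predictors, `converged`
#'   flag, `n_params`, and the log-likelihood (penalized for Firth).
#' @export
fit_strategy <- function(t, spec, seed = 1L) {
  stopifnot(inherits(t, "patient_table"), inherits(spec, "strategy_spec"))
  if (spec$imputation != "none" && anyNA(as.data.frame(t$X)))
    t <- fcs_impute_single(t, seed = mix_seed(seed, 17L))
  recipe <- make_recipe(t, spec)
  if (spec$selection == "backward") return(backward_step(t, spec, recipe))
  fit_with_recipe(t, spec, recipe)
}

#' Maximum likelihood logistic regression strategy
#'
#' @inheritParams fit_strategy
#' @return A `fitted_strategy`; see [fit_strategy()].
#' @export
fit_mle_logistic <- function(t, spec = strategy_spec("mle"), seed = 1L) {
  spec$estimator <- "mle"
  fit_strategy(t, spec, seed)
}

#' Firth-penalized logistic regression strategy
#'
#' Coefficients maximize the Jeffreys-prior penalized log-likelihood
#' l(beta) + 0.5 log det I(beta); estimates stay finite under complete
#' separation and are shrunk relative to MLE. No intercept correction is
#' applied.
#'
#' @inheritParams fit_strategy
#' @return A `fitted_strategy`; see [fit_strategy()].
#' @export
fit_firth_logistic <- function(t, spec = strategy_spec("firth"), seed = 1L) {
  spec$estimator <- "firth"
  fit_strategy(t, spec, seed)
}

# Greedy block-wise backward elimination: repeatedly drop the non-forced
# predictor block (categorical dummies and spline pairs move as one block)
# with the largest likelihood-ratio p-value >= alpha, refitting each time.
# Ties break in schema order. Forced predictors guarantee a non-empty model.
backward_step <- function(t, spec, recipe) {
  sel <- names(recipe)
  bad <- setdiff(spec$forced, sel)
  if (length(bad)) stop("forced predictor(s) not in schema: ",
                        paste(bad, collapse = ", "))
  full <- fit_with_recipe(t, spec, recipe[sel])
  repeat {
    cand <- setdiff(sel, spec$forced)
    if (!length(cand)) break
    pvals <- vapply(cand, function(nm) {
      red <- fit_with_recipe(t, spec, recipe[setdiff(sel, nm)])
      df <- full$n_params - red$n_params
      stats::pchisq(2 * (full$loglik - red$loglik), df, lower.tail = FALSE)
    }, numeric(1))
    if (max(pvals) < spec$alpha) break
    sel <- setdiff(sel, cand[which.max(pvals)])
    full <- fit_with_recipe(t, spec, recipe[sel])
  }
  full
}

#' Backward elimination strategy
#'
#' @inheritParams fit_strategy
#' @return A `fitted_strategy` whose `selected` field lists the retained
#'   predictors; all forced predictors are retained by construction.
#' @export
backward_eliminate <- function(t, spec, seed = 1L) {
  spec$selection <- "backward"
  fit_strategy(t, spec, seed)
}

#' Linear predictor of a fitted strategy on (new) data
#'
#' Applies the stored design recipe — spline knots and dummy coding are taken
#' from the model, never re-estimated — and returns
#' `intercept + design %*% coefficients`.
#'
#' @param object A `fitted_strategy`.
#' @param newdata A [patient_table()] or a `data.frame` of predictor columns.
#' @return Numeric vector of linear predictors.
#' @export
predict_lp <- function(object, newdata) {
  stopifnot(inherits(object, "fitted_strategy"))
  X <- if (inherits(newdata, "patient_table")) newdata$X else as.data.frame(newdata)
  Xd <- build_design(object$recipe, X)
  drop(object$intercept +
         Xd[, names(object$coefficients), drop = FALSE] %*% object$coefficients)
}

#' @export
print.fitted_strategy <- function(x, ...) {
  cat("fitted_strategy (", x$estimator,
      if (x$spec$use_splines) " + splines", ")\n", sep = "")
  cat("n =", x$n, " events =", x$events, " parameters =", x$n_params,
      " converged =", x$converged, "\n")
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' Export a fitted strategy as JSON
#'
#' Serializes intercept, coefficients, stored knots, and the selected
#' predictor set for reuse outside R.
#'
#' @param object A `fitted_strategy`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
model_to_json <- function(object, path = NULL) {
  stopifnot(inherits(object, "fitted_strategy"))
  knots <- Filter(Negate(is.null), lapply(object$recipe, `[[`, "knots"))
  x <- list(estimator = object$estimator, intercept = object$intercept,
            coefficients = as.list(object$coefficients),
            knots = knots, selected = object$selected,
            n = object$n, events = object$events,
            converged = object$converged)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
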