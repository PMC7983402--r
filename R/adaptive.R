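#' Define a stopping rule on bootstrap-corrected performance
#'
#' Accrual stops once the corrected calibration slope is at least
#' `slope_min` and the AUC optimism is at most `optimism_max` on
#' `consecutive` consecutive assessments. Thresholds are inclusive.
#'
#' @param slope_min Minimum corrected calibration slope (default 0.9).
#' @param optimism_max Maximum AUC optimism (0.02 for the default rule; a
#'   stricter 0.01 variant is common).
#' @param consecutive Number of consecutive satisfying assessments required
#'   (default 2, damping the batch-to-batch sampling noise).
#' @param name Optional label; defaults to a threshold-derived one.
#' @return An object of class `stopping_rule`.
#' @export
stopping_rule <- function(slope_min = 0.9, optimism_max = 0.02,
                          consecutive = 2L, name = NULL) {
  stopifnot(slope_min > 0, slope_min <= 1, optimism_max >= 0, consecutive >= 1L)
  if (is.null(name))
    name <- sprintf("slope%.2g_opt%.3g", slope_min, optimism_max)
  structure(list(slope_min = slope_min, optimism_max = optimism_max,
                 consecutive = as.integer(consecutive), name = name),
            class = "stopping_rule")
}

#' Accrual settings for the adaptive procedure
#'
#' @param n_start Sample size of the first assessment (default 100).
#' @param n_add Batch size added between assessments (default 50).
#' @param n_max Accrual cap (default 3000).
#' @param B Bootstrap replicates per assessment (default 200).
#' @return An object of class `accrual_config`.
#' @export
accrual_config <- function(n_start = 100L, n_add = 50L, n_max = 3000L,
                           B = 200L) {
  stopifnot(n_start >= 2L, n_add >= 1L, n_max >= n_start, B >= 1L)
  structure(list(n_start = as.integer(n_start), n_add = as.integer(n_add),
                 n_max = as.integer(n_max), B = as.integer(B)),
            class = "accrual_config")
}

#' Evaluate a stopping rule on an assessment history
#'
#' An assessment satisfies the rule instantaneously when
#' `slope_corrected >= slope_min` and `auc_optimism <= optimism_max` (both
#' inclusive). The rule is met when the last `consecutive` assessments all
#' satisfy it; an undefined assessment (failed fit or metric) breaks the
#' run and resets the consecutive count.
#'
#' @param history `data.frame` with columns `slope_corrected` and
#'   `auc_optimism`, one row per assessment in order (latest last). `NA`
#'   marks an undefined assessment.
#' @param rule A [stopping_rule()].
#' @return One of `"met_consecutive"`, `"met_instantaneous"`, `"not_met"`,
#'   `"undefined"` for the latest assessment.
#' @export
evaluate_rule <- function(history, rule) {
  stopifnot(nrow(history) >= 1L, inherits(rule, "stopping_rule"))
  k <- nrow(history)
  inst <- history$slope_corrected >= rule$slope_min &
    history$auc_optimism <= rule$optimism_max
  und <- is.na(inst)
  inst[und] <- FALSE
  if (und[k]) return("undefined")
  if (!inst[k]) return("not_met")
  if (k >= rule$consecutive &&
      all(inst[(k - rule$consecutive + 1L):k])) "met_consecutive"
  else "met_instantaneous"
}

#' Run the adaptive sample size procedure
#'
#' Grows the development dataset by prefix — the first `n_start` rows of
#' `source`, then `n_add` more at a time — and at every size applies the
#' complete modeling strategy, internally validates it with the enhanced
#' bootstrap, and evaluates every stopping rule on the corrected calibration
#' slope and AUC optimism. The model at the assessment that completes a
#' rule's consecutive requirement is that rule's final prediction model.
#'
#' `source` supplies the accrual order: in a prospective study it is the
#' recruitment order; the resampling harness ([run_repetition()]) passes a
#' without-replacement permutation of a population.
#'
#' @param source A [patient_table()] whose row order is the accrual stream.
#' @param spec A [strategy_spec()].
#' @param acc An [accrual_config()].
#' @param rules List of [stopping_rule()] objects (a single rule is also
#'   accepted).
#' @param seed Integer root seed; each assessment's bootstrap runs on its
#'   own substream.
#' @param exhaust When `TRUE` (default) accrual continues to `n_max` even
#'   after all rules are met, giving learning curves of fixed length; when
#'   `FALSE` accrual stops at the first assessment where any rule is met.
#' @param min_n Optional advisory minimum (e.g. a fixed a-priori sample size
#'   N0 from [riley_min_n()]); when given, rules cannot stop accrual before
#'   it, though their status is still recorded.
#' @return An object of class `learning_curve`: `assessments` (one row per
#'   assessment: n, events, EPP, apparent/corrected AUC and slope, optimism,
#'   bootstrap bookkeeping, one status column per rule), `stop_n` (named
#'   vector, `NA` when a rule was never met), `final_models` (per rule),
#'   `models` (per assessment), and `truncated_at`.
#' @export
run_adaptive <- function(source, spec, acc, rules, seed = 1L, exhaust = TRUE,
                         min_n = NULL) {
  stopifnot(inherits(source, "patient_table"), inherits(acc, "accrual_config"))
  if (inherits(rules, "stopping_rule")) rules <- list(rules)
  stopifnot(length(rules) >= 1L)
  rule_names <- vapply(rules, `[[`, "", "name")
  if (anyDuplicated(rule_names)) stop("stopping rule names must be unique")
  if (source$n < acc$n_start)
    stop("accrual source has fewer than n_start = ", acc$n_start, " rows")
  sizes <- seq.int(acc$n_start, min(acc$n_max, source$n), by = acc$n_add)
  p_cand <- candidate_params(source$meta, spec)

  rows <- vector("list", length(sizes))
  models <- vector("list", length(sizes))
  stop_n <- stats::setNames(rep(NA_real_, length(rules)), rule_names)
  final_models <- stats::setNames(vector("list", length(rules)), rule_names)
  hist <- data.frame(slope_corrected = numeric(0), auc_optimism = numeric(0))
  n_fail <- 0L

  for (k in seq_along(sizes)) {
    nk <- sizes[k]
    tk <- source[seq_len(nk)]
    pe <- tryCatch(
      suppressWarnings(enhanced_bootstrap(tk, spec, B = acc$B,
                                          seed = mix_seed(seed, 131L * k))),
      error = function(e) NULL)
    if (is.null(pe)) {
      n_fail <- n_fail + 1L
      hist <- rbind(hist, data.frame(slope_corrected = NA_real_,
                                     auc_optimism = NA_real_))
      row <- data.frame(k = k, n = nk, events = sum(tk$y),
                        epp = sum(tk$y) / p_cand,
                        auc_apparent = NA_real_, auc_corrected = NA_real_,
                        auc_optimism = NA_real_, slope_apparent = NA_real_,
                        slope_corrected = NA_real_, B_used = 0L,
                        failed_replicates = acc$B)
    } else {
      hist <- rbind(hist, data.frame(slope_corrected = pe$slope_corrected,
                                     auc_optimism = pe$auc_optimism))
      models[[k]] <- pe$model
      row <- data.frame(k = k, n = nk, events = pe$events,
                        epp = pe$events / p_cand,
                        auc_apparent = pe$auc_apparent,
                        auc_corrected = pe$auc_corrected,
                        auc_optimism = pe$auc_optimism,
                        slope_apparent = pe$slope_apparent,
                        slope_corrected = pe$slope_corrected,
                        B_used = pe$B_used,
                        failed_replicates = pe$failed_replicates)
    }
    any_met <- FALSE
    for (j in seq_along(rules)) {
      st <- evaluate_rule(hist, rules[[j]])
      row[[paste0("status_", rule_names[j])]] <- st
      if (st == "met_consecutive" &&
          (is.null(min_n) || nk >= min_n) && is.na(stop_n[j])) {
        stop_n[j] <- nk
        final_models[[j]] <- models[[k]]
        any_met <- TRUE
      }
    }
    rows[[k]] <- row
    if (!exhaust && any_met) {
      rows <- rows[seq_len(k)]
      models <- models[seq_len(k)]
      break
    }
  }
  if (n_fail == length(rows))
    stop("adaptive procedure failed: every assessment failed")
  assessments <- do.call(rbind, rows)
  rownames(assessments) <- NULL
  structure(list(assessments = assessments, rules = rules, stop_n = stop_n,
                 final_models = final_models, models = models,
                 truncated_at = if (anyNA(stop_n)) max(assessments$n) else NA,
                 spec = spec, acc = acc, seed = seed,
                 candidate_params = p_cand),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("learning_curve:", nrow(x$assessments), "assessments, n =",
      min(x$assessments$n), "to", max(x$assessments$n), "\n")
  for (nm in names(x$stop_n)) {
    cat("  rule", nm, ":",
        if (is.na(x$stop_n[nm])) "not met" else paste("stop at n =", x$stop_n[nm]),
        "\n")
  }
  invisible(x)
}

#' Plot a learning curve
#'
#' Three stacked panels: corrected AUC, AUC optimism, and corrected
#' calibration slope against cumulative sample size, with stopping-rule
#' thresholds as reference lines.
#'
#' @param x A `learning_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.learning_curve <- function(x, ...) {
  a <- x$assessments
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(a$n, a$auc_corrected, type = "b", pch = 16, cex = 0.6,
                 xlab = "sample size", ylab = "corrected AUC", ...)
  graphics::plot(a$n, a$auc_optimism, type = "b", pch = 16, cex = 0.6,
                 xlab = "sample size", ylab = "AUC optimism", ...)
  for (r in x$rules) graphics::abline(h = r$optimism_max, lty = 3)
  graphics::plot(a$n, a$slope_corrected, type = "b", pch = 16, cex = 0.6,
                 xlab = "sample size", ylab = "corrected slope", ...)
  graphics::abline(h = 1, lty = 2)
  for (r in x$rules) graphics::abline(h = r$slope_min, lty = 3)
  invisible(x)
}

#' Write a learning curve to CSV / JSON
#'
#' One CSV row per assessment plus a JSON summary (stop_n per rule and the
#' final model coefficients).
#'
#' @param x A `learning_curve`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the assessment `data.frame`.
#' @export
write_learning_curve <- function(x, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "learning_curve"))
  if (!is.null(csv_path))
    utils::write.csv(x$assessments, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    fm <- lapply(x$final_models, function(m) {
      if (is.null(m)) return(NULL)
      c(list(`(Intercept)` = m$intercept), as.list(m$coefficients))
    })
    js <- jsonlite::toJSON(list(stop_n = as.list(x$stop_n),
                                final_models = fm),
                           auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(js, json_path)
  }
  invisible(x$assessments)
}
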