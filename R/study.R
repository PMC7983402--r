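#' One resampling-study repetition with holdout evaluation
#'
#' Draws a uniform random permutation of a fixed population; its first
#' `acc$n_max` rows form the accrual stream consumed by [run_adaptive()]
#' (so within a repetition patients are sampled without replacement), and
#' the remaining rows — never entering the development set of this
#' repetition — serve as the holdout sample. At every assessment the
#' interim model is additionally evaluated (AUC, calibration slope) on the
#' holdout.
#'
#' @param pop A [patient_table()] population with more than `acc$n_max`
#'   rows.
#' @param spec A [strategy_spec()].
#' @param acc An [accrual_config()].
#' @param rules List of [stopping_rule()]s.
#' @param rep_seed Integer seed; identical seeds reproduce the repetition
#'   exactly.
#' @param exhaust Passed to [run_adaptive()]; the study default `TRUE`
#'   yields fixed-length learning curves.
#' @return List with `curve` (a `learning_curve`), `holdout` (per-assessment
#'   `data.frame` of holdout AUC and slope), `holdout_n`, and the
#'   development/holdout row indices (`dev_rows`, `holdout_rows`).
#' @export
run_repetition <- function(pop, spec, acc, rules, rep_seed = 1L,
                           exhaust = TRUE) {
  stopifnot(inherits(pop, "patient_table"))
  if (pop$n < acc$n_max + 1L)
    stop("population must exceed the accrual cap n_max = ", acc$n_max)
  perm <- with_seed(mix_seed(rep_seed, 1L), sample.int(pop$n))
  dev <- pop[perm[seq_len(acc$n_max)]]
  hold <- pop[perm[(acc$n_max + 1L):pop$n]]
  curve <- run_adaptive(dev, spec, acc, rules,
                        seed = mix_seed(rep_seed, 2L), exhaust = exhaust)
  a <- curve$assessments
  hd <- lapply(seq_len(nrow(a)), function(k) {
    m <- curve$models[[k]]
    out <- c(auc = NA_real_, slope = NA_real_)
    if (!is.null(m))
      out <- tryCatch(eval_perf(m, hold), error = function(e) out)
    data.frame(k = a$k[k], n = a$n[k], holdout_auc = unname(out["auc"]),
               holdout_slope = unname(out["slope"]))
  })
  list(curve = curve, holdout = do.call(rbind, hd), holdout_n = hold$n,
       dev_rows = perm[seq_len(acc$n_max)],
       holdout_rows = perm[(acc$n_max + 1L):pop$n])
}

#' Run the full resampling study
#'
#' Repeats [run_repetition()] `repetitions` times with independent,
#' seed-derived permutations of the population, then summarizes stopping
#' sample sizes and final-model performance per rule (median and IQR) and
#' averages the learning and holdout curves pointwise.
#'
#' @param pop A [patient_table()] population, or a (calibrated or not)
#'   `scenario_config` from which `pop_size` patients are generated.
#' @param spec,acc,rules As in [run_repetition()].
#' @param repetitions Number of repetitions (desk-scale default 20; a
#'   full-scale evaluation would use several hundred).
#' @param root_seed Integer; repetition r runs on a substream derived from
#'   `(root_seed, r)`, so results are independent of scheduling.
#' @param exhaust Passed through to [run_adaptive()].
#' @return An object of class `study_result`: `repetitions` (list of
#'   repetition outputs), `summary` (see [summarize_study()]), and the
#'   configuration.
#' @export
run_study <- function(pop, spec, acc, rules, repetitions = 20L,
                      root_seed = 1L, exhaust = TRUE) {
  if (inherits(pop, "scenario_config")) {
    if (!pop$calibrated) pop <- calibrate_scenario(pop)
    pop <- generate_population(pop)
  }
  if (inherits(rules, "stopping_rule")) rules <- list(rules)
  stopifnot(repetitions >= 1L)
  reps <- lapply(seq_len(repetitions), function(r)
    run_repetition(pop, spec, acc, rules,
                   rep_seed = mix_seed(root_seed, 5000L + r),
                   exhaust = exhaust))
  structure(list(repetitions = reps,
                 summary = summarize_study(reps, rules),
                 spec = spec, acc = acc, rules = rules,
                 root_seed = root_seed, n_pop = pop$n),
            class = "study_result")
}

# quartiles by linear interpolation between order statistics (type 7),
# the package's fixed convention so IQRs are reproducible bit-exactly
quart <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                     names = FALSE, na.rm = TRUE)

#' Summarize a resampling study
#'
#' Medians and interquartile ranges across repetitions of the stopping
#' sample size, events per parameter, and bootstrap-corrected AUC and
#' calibration slope of the final model, per stopping rule; repetitions
#' where a rule was never met are excluded from those summaries and counted
#' as censored at the accrual cap. Also returns the pointwise average
#' learning curve and average holdout curve.
#'
#' @param reps List of [run_repetition()] outputs.
#' @param rules The stopping rules used.
#' @return List with `per_rule` (`data.frame`: median/IQR of stop_n, EPP,
#'   corrected AUC, corrected slope, and `censored` count), `avg_curve`,
#'   and `avg_holdout`.
#' @export
summarize_study <- function(reps, rules) {
  if (inherits(rules, "stopping_rule")) rules <- list(rules)
  rule_names <- vapply(rules, `[[`, "", "name")
  per_rule <- do.call(rbind, lapply(rule_names, function(nm) {
    at_stop <- lapply(reps, function(r) {
      sn <- r$curve$stop_n[[nm]]
      if (is.na(sn)) return(NULL)
      a <- r$curve$assessments
      a[a$n == sn, c("n", "epp", "auc_corrected", "slope_corrected")]
    })
    censored <- sum(vapply(at_stop, is.null, logical(1)))
    at_stop <- do.call(rbind, at_stop)
    if (is.null(at_stop) || nrow(at_stop) == 0L) {
      return(data.frame(rule = nm, stop_n_q25 = NA, stop_n = NA,
                        stop_n_q75 = NA, epp_q25 = NA, epp = NA, epp_q75 = NA,
                        auc_q25 = NA, auc = NA, auc_q75 = NA,
                        slope_q25 = NA, slope = NA, slope_q75 = NA,
                        censored = censored))
    }
    qs <- lapply(at_stop, quart)
    data.frame(rule = nm,
               stop_n_q25 = qs$n[1], stop_n = qs$n[2], stop_n_q75 = qs$n[3],
               epp_q25 = qs$epp[1], epp = qs$epp[2], epp_q75 = qs$epp[3],
               auc_q25 = qs$auc_corrected[1], auc = qs$auc_corrected[2],
               auc_q75 = qs$auc_corrected[3],
               slope_q25 = qs$slope_corrected[1],
               slope = qs$slope_corrected[2],
               slope_q75 = qs$slope_corrected[3],
               censored = censored)
  }))
  rownames(per_rule) <- NULL
  curves <- lapply(reps, function(r) r$curve$assessments)
  ns <- sort(unique(unlist(lapply(curves, `[[`, "n"))))
  colm <- function(dfl, col, n) {
    mean(unlist(lapply(dfl, function(a) a[[col]][a$n == n])), na.rm = TRUE)
  }
  avg_curve <- data.frame(
    n = ns,
    auc_corrected = vapply(ns, function(n) colm(curves, "auc_corrected", n), 0),
    auc_optimism = vapply(ns, function(n) colm(curves, "auc_optimism", n), 0),
    slope_corrected = vapply(ns, function(n) colm(curves, "slope_corrected", n), 0))
  holds <- lapply(reps, `[[`, "holdout")
  avg_holdout <- data.frame(
    n = ns,
    holdout_auc = vapply(ns, function(n) colm(holds, "holdout_auc", n), 0),
    holdout_slope = vapply(ns, function(n) colm(holds, "holdout_slope", n), 0))
  list(per_rule = per_rule, avg_curve = avg_curve, avg_holdout = avg_holdout)
}

#' Bootstrap-corrected versus holdout performance
#'
#' Per-assessment difference between the average bootstrap-corrected and the
#' average holdout estimate for AUC and calibration slope, together with the
#' maximum absolute difference over the final third of the learning curve
#' (the agreement zone once optimism has largely vanished).
#'
#' @param x A `study_result`.
#' @return `data.frame` with columns `n`, `d_auc`, `d_slope`; attributes
#'   `max_abs_d_auc_final_third` and `max_abs_d_slope_final_third`.
#' @export
compare_corrected_vs_holdout <- function(x) {
  stopifnot(inherits(x, "study_result"))
  s <- x$summary
  d <- data.frame(n = s$avg_curve$n,
                  d_auc = s$avg_curve$auc_corrected - s$avg_holdout$holdout_auc,
                  d_slope = s$avg_curve$slope_corrected -
                    s$avg_holdout$holdout_slope)
  last <- d[d$n >= stats::quantile(d$n, 2 / 3, type = 7), , drop = FALSE]
  attr(d, "max_abs_d_auc_final_third") <- max(abs(last$d_auc), na.rm = TRUE)
  attr(d, "max_abs_d_slope_final_third") <- max(abs(last$d_slope), na.rm = TRUE)
  d
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result:", length(x$repetitions), "repetitions, population",
      x$n_pop, "\n")
  print(x$summary$per_rule, digits = 3)
  invisible(x)
}

#' Plot average learning and holdout curves of a study
#'
#' @param x A `study_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.study_result <- function(x, ...) {
  s <- x$summary
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(s$avg_curve$n, s$avg_curve$auc_corrected, type = "l",
                 xlab = "sample size", ylab = "AUC", ...)
  graphics::lines(s$avg_holdout$n, s$avg_holdout$holdout_auc, lty = 2)
  graphics::legend("bottomright", c("bootstrap-corrected", "holdout"),
                   lty = 1:2, bty = "n")
  graphics::plot(s$avg_curve$n, s$avg_curve$slope_corrected, type = "l",
                 xlab = "sample size", ylab = "calibration slope", ...)
  graphics::lines(s$avg_holdout$n, s$avg_holdout$holdout_slope, lty = 2)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
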