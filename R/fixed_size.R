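#' Maximum attainable Cox-Snell R-squared
#'
#' The Cox-Snell R-squared of a binary-outcome model is bounded above by
#' `1 - (phi^phi (1-phi)^(1-phi))^2`, a function of the event fraction only.
#'
#' @param phi Event fraction in (0, 1).
#' @return Upper bound on the Cox-Snell R-squared.
#' @export
cox_snell_r2_max <- function(phi) {
  stopifnot(phi > 0, phi < 1)
  1 - (phi^phi * (1 - phi)^(1 - phi))^2
}

#' Events-per-parameter sample size
#'
#' The classical rule of thumb: `ceiling(epp * p / phi)` patients are needed
#' for `epp` events per candidate parameter with `p` candidate parameters
#' and event fraction `phi`. Fractional counts are rounded up.
#'
#' @param epp Target events per candidate parameter (e.g. 10).
#' @param p Number of candidate model parameters (excluding intercept).
#' @param phi Anticipated event fraction in (0, 1).
#' @return Required number of patients (integer).
#' @examples
#' epp_sample_size(10, 7, 1931 / 5914)   # 215
#' epp_sample_size(10, 12, 2127 / 4888)  # 276
#' @export
epp_sample_size <- function(epp, p, phi) {
  stopifnot(epp > 0, p >= 1)
  if (!(phi > 0 && phi < 1)) stop("event fraction must lie in (0, 1)")
  as.integer(ceiling(epp * p / phi))
}

#' Fixed a-priori minimum sample size (Cox-Snell R-squared criteria)
#'
#' The three-criteria minimum sample size calculation for binary prediction
#' models, used as the initial estimate N0 of the adaptive procedure:
#' \enumerate{
#'   \item global shrinkage of at least `S`:
#'     `n1 = p / ((S - 1) * ln(1 - r2cs / S))`;
#'   \item small absolute optimism `delta` in apparent R-squared: the same
#'     formula with `S` replaced by `r2cs / (r2cs + delta * r2cs_max(phi))`;
#'   \item precise overall risk estimate:
#'     `n3 = (1.96 / margin)^2 * phi * (1 - phi)`.
#' }
#' The result is the ceiling of the largest criterion. The anticipated
#' Cox-Snell R-squared is a required input: it must be argued from the
#' modeling context (e.g. from a published model's performance), and the
#' returned sample size is conditional on it.
#'
#' @param p Candidate parameters (excluding intercept).
#' @param phi Anticipated event fraction in (0, 1).
#' @param r2cs Anticipated Cox-Snell R-squared, below [cox_snell_r2_max()].
#' @param S Shrinkage target (default 0.9).
#' @param delta Allowed optimism in apparent R-squared (default 0.05).
#' @param margin Absolute margin for the overall risk estimate (default
#'   0.05, with a fixed 95% z-value of 1.96).
#' @return List with `n_total`, the per-criterion breakdown
#'   `n_by_criterion`, the unrounded values `raw`, and `epp_implied`
#'   (`n_total * phi / p`).
#' @export
riley_min_n <- function(p, phi, r2cs, S = 0.9, delta = 0.05, margin = 0.05) {
  stopifnot(p >= 1, S > 0, S < 1, delta > 0, margin > 0)
  if (!(phi > 0 && phi < 1)) stop("event fraction must lie in (0, 1)")
  r2max <- cox_snell_r2_max(phi)
  if (!(r2cs > 0 && r2cs < r2max))
    stop(sprintf("anticipated r2cs must lie in (0, %.4f) for phi = %.3f",
                 r2max, phi))
  n1 <- p / ((S - 1) * log(1 - r2cs / S))
  S2 <- r2cs / (r2cs + delta * r2max)
  n2 <- p / ((S2 - 1) * log(1 - r2cs / S2))
  n3 <- (1.96 / margin)^2 * phi * (1 - phi)
  raw <- c(shrinkage = n1, r2_optimism = n2, risk_margin = n3)
  n_total <- as.integer(ceiling(max(raw)))
  list(n_total = n_total,
       n_by_criterion = as.integer(ceiling(raw)),
       raw = raw,
       epp_implied = n_total * phi / p)
}

#' Round a sample size up to the next accrual batch
#'
#' When patients are analyzed in batches of `batch`, a fixed sample size is
#' reached at the next multiple of the batch size.
#'
#' @param n Required sample size.
#' @param batch Batch size (>= 1).
#' @return Smallest multiple of `batch` that is `>= n`.
#' @examples
#' round_to_batch(314, 50)  # 350
#' round_to_batch(669, 50)  # 700
#' @export
round_to_batch <- function(n, batch) {
  stopifnot(batch >= 1, n >= 0)
  as.integer(batch * ceiling(n / batch))
}

#' Print a fixed sample size table
#'
#' Convenience formatter combining [epp_sample_size()] and [riley_min_n()]
#' with batch rounding; used by the command-line interface.
#'
#' @inheritParams riley_min_n
#' @param epp EPP targets to tabulate.
#' @param batch Accrual batch for rounding.
#' @return `data.frame` with one row per method (invisibly printed).
#' @export
fixed_size_table <- function(p, phi, r2cs = NULL, epp = 10, batch = 50,
                             S = 0.9, delta = 0.05, margin = 0.05) {
  rows <- lapply(epp, function(e) {
    n <- epp_sample_size(e, p, phi)
    data.frame(method = sprintf("%g EPP", e), n = n,
               n_batched = round_to_batch(n, batch),
               epp_implied = n * phi / p)
  })
  if (!is.null(r2cs)) {
    r <- riley_min_n(p, phi, r2cs, S = S, delta = delta, margin = margin)
    rows <- c(rows, list(data.frame(
      method = sprintf("min-n criteria (r2cs = %.3g)", r2cs),
      n = r$n_total, n_batched = round_to_batch(r$n_total, batch),
      epp_implied = r$epp_implied)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
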