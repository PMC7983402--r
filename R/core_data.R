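#' Describe one candidate predictor
#'
#' A predictor schema entry records how a column of the patient table enters
#' the model: its measurement type, whether it is forced into the model
#' (never removed by backward elimination), and whether it is eligible for
#' restricted-cubic-spline expansion.
#'
#' @param name Column name in the patient table.
#' @param type One of `"continuous"`, `"binary"`, `"categorical"`. Two-level
#'   variables are `"binary"`; `"categorical"` requires at least 3 levels and
#'   is reference-coded (first level is the reference) at design-matrix time.
#' @param levels Ordered character vector of levels (categorical only).
#' @param forced Logical; forced predictors survive backward elimination.
#' @param spline Logical; eligible for spline expansion (continuous only).
#'   The expansion is only applied by strategies with `use_splines = TRUE`.
#' @return An object of class `predictor_meta`.
#' @seealso [patient_table()], [strategy_spec()]
#' @export
predictor_meta <- function(name,
                           type = c("continuous", "binary", "categorical"),
                           levels = NULL, forced = FALSE, spline = FALSE) {
  type <- match.arg(type)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (isTRUE(spline) && type != "continuous")
    stop("spline expansion requires a continuous predictor: ", name)
  if (type == "categorical") {
    if (is.null(levels) || length(levels) < 3L)
      stop("categorical predictor '", name,
           "' needs at least 3 levels; 2-level variables are binary")
    levels <- as.character(levels)
    if (anyDuplicated(levels)) stop("duplicated levels for '", name, "'")
  } else if (!is.null(levels)) {
    stop("levels are only meaningful for categorical predictors ('", name, "')")
  }
  structure(list(name = name, type = type, levels = levels,
                 forced = isTRUE(forced), spline = isTRUE(spline)),
            class = "predictor_meta")
}

meta_names <- function(meta) vapply(meta, `[[`, "", "name")

#' Construct a validated patient table
#'
#' The central data container: a binary outcome vector plus one column per
#' candidate predictor, typed according to a predictor schema. Missing cells
#' are represented by `NA` (never by sentinel numbers); [missing_mask()]
#' exposes them as a logical matrix.
#'
#' @param y Binary outcome vector coded 0/1 (1 = event), no missing values.
#' @param X `data.frame` of predictor columns; names and order must match
#'   `meta`.
#' @param meta List of [predictor_meta()] entries (the schema).
#' @return An object of class `patient_table` with fields `y`, `X`, `meta`,
#'   `n`.
#' @examples
#' meta <- list(predictor_meta("age", "continuous"),
#'              predictor_meta("ascites", "binary"))
#' t <- patient_table(y = c(0, 1, 0), X = data.frame(age = c(40, 60, 55),
#'                    ascites = c(0, 1, 0)), meta = meta)
#' event_fraction(t)
#' @export
patient_table <- function(y, X, meta) {
  if (!is.data.frame(X)) X <- as.data.frame(X)
  y <- as.numeric(y)
  if (length(y) == 0L) stop("empty outcome vector")
  if (anyNA(y)) stop("outcome must be fully observed")
  if (!all(y %in% c(0, 1)))
    stop("outcome is not binary 0/1; offending values: ",
         paste(utils::head(setdiff(unique(y), c(0, 1)), 3), collapse = ", "))
  nms <- meta_names(meta)
  if (!identical(names(X), nms)) {
    if (!all(nms %in% names(X)))
      stop("schema column(s) absent from data: ",
           paste(setdiff(nms, names(X)), collapse = ", "))
    X <- X[nms]
  }
  if (nrow(X) != length(y)) stop("outcome length and predictor rows differ")
  for (m in meta) {
    x <- X[[m$name]]
    if (m$type == "categorical") {
      x <- as.character(x)
      bad <- setdiff(unique(x[!is.na(x)]), m$levels)
      if (length(bad))
        stop("unknown level(s) in '", m$name, "': ", paste(bad, collapse = ", "))
      X[[m$name]] <- x
    } else {
      if (!is.numeric(x)) stop("column '", m$name, "' must be numeric")
      if (m$type == "binary" && !all(x[!is.na(x)] %in% c(0, 1)))
        stop("binary column '", m$name, "' has values outside {0,1}")
      X[[m$name]] <- as.numeric(x)
    }
  }
  rownames(X) <- NULL
  structure(list(y = y, X = X, meta = meta, n = length(y)),
            class = "patient_table")
}

#' @export
`[.patient_table` <- function(x, i) {
  # row subset; no revalidation (hot path inside the bootstrap)
  X <- x$X[i, , drop = FALSE]
  rownames(X) <- NULL
  structure(list(y = x$y[i], X = X, meta = x$meta, n = nrow(X)),
            class = "patient_table")
}

#' @export
print.patient_table <- function(x, ...) {
  cat("patient_table:", x$n, "patients,", sum(x$y), "events (",
      sprintf("%.1f%%", 100 * mean(x$y)), ")\n")
  cat("predictors:", paste(meta_names(x$meta), collapse = ", "), "\n")
  nm <- sum(is.na(as.matrix(x$X)))
  if (nm > 0) cat("missing cells:", nm, "\n")
  invisible(x)
}

#' Per-cell missingness indicator
#'
#' @param t A [patient_table()].
#' @return Logical matrix, `TRUE` where a predictor cell is missing.
#' @export
missing_mask <- function(t) {
  stopifnot(inherits(t, "patient_table"))
  mask <- vapply(t$X, is.na, logical(t$n))
  if (t$n == 1L) mask <- matrix(mask, nrow = 1L, dimnames = list(NULL, names(t$X)))
  mask
}

#' Event fraction of a patient table
#'
#' The outcome prevalence/incidence phi = events / n.
#'
#' @param t A [patient_table()].
#' @return Proportion of events in `[0, 1]`.
#' @export
event_fraction <- function(t) {
  stopifnot(inherits(t, "patient_table"))
  if (t$n == 0L) stop("empty table")
  mean(t$y)
}

n_events <- function(t) sum(t$y)

#' Read a patient table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row, `.` as decimal
#' mark, and empty cells (or `NA`) for missing predictor values. The outcome
#' must be coded 0/1, or as two labels mapped via `event_level`.
#'
#' @param path CSV file path.
#' @param schema List of [predictor_meta()] entries.
#' @param outcome Name of the outcome column.
#' @param event_level Optional label identifying the event when the outcome
#'   column is non-numeric with exactly two labels.
#' @return A [patient_table()]; row order is preserved.
#' @export
read_patient_table <- function(path, schema, outcome, event_level = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), colClasses = "character",
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("no data rows in ", path)
  need <- c(outcome, meta_names(schema))
  if (!all(need %in% names(df)))
    stop("schema column(s) absent from file: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  yraw <- df[[outcome]]
  if (anyNA(yraw)) stop("outcome column contains missing values")
  if (!is.null(event_level)) {
    labs <- unique(yraw)
    if (length(labs) != 2L)
      stop("event_level mapping requires exactly two outcome labels")
    y <- as.numeric(yraw == event_level)
  } else {
    y <- suppressWarnings(as.numeric(yraw))
    if (anyNA(y) || !all(y %in% c(0, 1)))
      stop("outcome column is not coded 0/1: ",
           paste(utils::head(setdiff(unique(yraw), c("0", "1")), 3),
                 collapse = ", "))
  }
  X <- df[meta_names(schema)]
  for (m in schema) {
    if (m$type != "categorical") {
      raw <- X[[m$name]]
      num <- suppressWarnings(as.numeric(raw))
      if (any(is.na(num) & !is.na(raw)))
        stop("non-numeric value in column '", m$name, "'")
      X[[m$name]] <- num
    }
  }
  patient_table(y, X, schema)
}

#' Write a patient table to CSV
#'
#' Continuous values are written with 17 significant digits so a write/read
#' round trip reproduces the table bit-exactly; missing cells are written as
#' empty fields.
#'
#' @param t A [patient_table()].
#' @param path Output file path.
#' @param outcome Name used for the outcome column.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(t, path, outcome = "y") {
  stopifnot(inherits(t, "patient_table"))
  out <- data.frame(row.names = seq_len(t$n))
  out[[outcome]] <- as.character(t$y)
  for (m in t$meta) {
    x <- t$X[[m$name]]
    col <- if (m$type == "categorical") as.character(x) else sprintf("%.17g", x)
    col[is.na(x)] <- NA_character_
    out[[m$name]] <- col
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a run configuration file
#'
#' A single YAML file describes a full run: outcome name, predictor schema
#' (type/forced/spline flags), modeling strategy, accrual settings, stopping
#' rules and seed. Used by the command-line scripts; all keys map onto
#' [predictor_meta()], [strategy_spec()], [accrual_config()] and
#' [stopping_rule()] arguments.
#'
#' @param path YAML file path.
#' @return List with elements `outcome`, `event_level`, `schema`, `spec`,
#'   `acc`, `rules`, `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  schema <- lapply(cfg$predictors, function(p) {
    predictor_meta(p$name, p$type %||% "continuous", levels = p$levels,
                   forced = isTRUE(p$forced), spline = isTRUE(p$spline))
  })
  s <- cfg$strategy %||% list()
  spec <- strategy_spec(
    estimator  = s$estimator %||% "mle",
    use_splines = isTRUE(s$use_splines),
    selection  = s$selection %||% "none",
    alpha      = s$alpha %||% 0.05,
    forced     = unlist(lapply(schema, function(m) if (m$forced) m$name)) %||% character(),
    imputation = s$imputation %||% "none",
    m          = s$m %||% 5L)
  a <- cfg$accrual %||% list()
  acc <- accrual_config(n_start = a$n_start %||% 100L, n_add = a$n_add %||% 50L,
                        n_max = a$n_max %||% 3000L, B = a$B %||% 200L)
  rules <- lapply(cfg$rules %||% list(list()), function(r) {
    stopping_rule(slope_min = r$slope_min %||% 0.9,
                  optimism_max = r$optimism_max %||% 0.02,
                  consecutive = r$consecutive %||% 2L, name = r$name)
  })
  outcome <- cfg$outcome %||% "y"
  # YAML 1.1 reads a bare y/n as a boolean; map it back to the column name
  if (is.logical(outcome)) outcome <- if (outcome) "y" else "n"
  list(outcome = outcome, event_level = cfg$event_level,
       schema = schema, spec = spec, acc = acc, rules = rules,
       seed = as.integer(cfg$seed %||% 1L), extra = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
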