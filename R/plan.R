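# Factor specifications and their assignment onto orthogonal-array columns.

#' Declare an experimental factor
#'
#' A factor is a tunable quantity (hyperparameter) with 2 or 3 discrete
#' levels. Numeric levels must be strictly increasing. A factor can be
#' flagged `structural` when it describes model capacity (e.g. hidden-layer
#' count): the two-stage driver fixes a structural factor instead of
#' refining it when its best level is the smallest one.
#'
#' @param name Unique factor name.
#' @param levels Ordered vector of 2 or 3 level values (numeric or labels).
#' @param role `"categorical"`, `"numeric"` (continuous) or `"integer"`.
#' @param structural Logical; see Description.
#' @param lower,upper Optional hard bounds for numeric refinement; refined
#'   levels are clipped to them (with a warning).
#' @return A `tsto_factor` object.
#' @examples
#' factor_spec("learning_rate", c(0.2, 0.3, 0.4), role = "numeric")
#' factor_spec("activation", c("logistic", "tanh", "relu"))
#' @export
factor_spec <- function(name, levels,
                        role = c("categorical", "numeric", "integer"),
                        structural = FALSE, lower = -Inf, upper = Inf) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n <- length(levels)
  if (n < 2L || n > 3L) {
    stop("Factor '", name, "' must have 2 or 3 levels, got ", n, call. = FALSE)
  }
  if (role != "categorical") {
    levels <- as.numeric(levels)
    if (any(is.na(levels))) {
      stop("Factor '", name, "' has non-numeric levels but role '", role, "'",
           call. = FALSE)
    }
    if (any(diff(levels) <= 0)) {
      stop("Numeric levels of factor '", name,
           "' must be strictly increasing", call. = FALSE)
    }
    if (role == "integer" && any(levels != round(levels))) {
      stop("Factor '", name, "' has role 'integer' but non-integer levels",
           call. = FALSE)
    }
  } else {
    levels <- as.character(levels)
    if (anyDuplicated(levels)) {
      stop("Duplicate levels in factor '", name, "'", call. = FALSE)
    }
  }
  structure(
    list(name = name, role = role, levels = levels,
         structural = isTRUE(structural), lower = lower, upper = upper),
    class = "tsto_factor"
  )
}

.check_factor_list <- function(factors) {
  stopifnot(is.list(factors), length(factors) >= 1L)
  ok <- vapply(factors, inherits, logical(1), "tsto_factor")
  if (!all(ok)) stop("All factors must be created by factor_spec()", call. = FALSE)
  nm <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("Factor names must be unique", call. = FALSE)
  names(factors) <- nm
  factors
}

#' Map factors onto orthogonal-array columns to realize an experiment plan
#'
#' Each factor is assigned to one array column (1-based); its level count
#' must equal the column's level count — factors with fewer levels than the
#' column are rejected rather than dummy-leveled. The realized design gives,
#' for every run, the concrete value of every factor:
#' `value(run, f) = levels(f)[matrix(run, col(f))]`. Unassigned columns are
#' recorded; their variation contributes residual degrees of freedom in the
#' ANOVA error term.
#'
#' @param factors List of [factor_spec()] objects.
#' @param array A `tsto_oa` array (or identifier string looked up with
#'   [oa_get()]).
#' @param assignment Named integer vector mapping factor name to column
#'   index. Default: factors on consecutive columns starting at the first
#'   column whose level counts match.
#' @return A `tsto_plan` object: `array`, `factors`, `assignment`,
#'   `design` (data frame `run` + one column per factor, realized values)
#'   and `unused_columns`.
#' @examples
#' f <- list(
#'   factor_spec("lr", c(0.25, 0.30, 0.35), role = "numeric"),
#'   factor_spec("momentum", c(0.85, 0.90, 0.95), role = "numeric"),
#'   factor_spec("nodes", c(6, 8, 10), role = "integer")
#' )
#' plan <- make_plan(f, "L9", assignment = c(lr = 1, momentum = 2, nodes = 3))
#' plan$design
#' @export
make_plan <- function(factors, array, assignment = NULL) {
  factors <- .check_factor_list(factors)
  if (is.character(array)) array <- oa_get(array)
  stopifnot(inherits(array, "tsto_oa"))
  nm <- names(factors)

  if (is.null(assignment)) {
    # greedy default: first unused column with a matching level count
    assignment <- integer(0)
    used <- integer(0)
    for (f in factors) {
      cand <- setdiff(which(array$levels_per_col == length(f$levels)), used)
      if (!length(cand)) {
        stop("No free ", length(f$levels), "-level column left in ",
             array$id, " for factor '", f$name, "'", call. = FALSE)
      }
      assignment[f$name] <- cand[1L]
      used <- c(used, cand[1L])
    }
  }
  assignment <- assignment[nm]
  if (any(is.na(assignment))) {
    stop("Assignment missing for factor(s): ",
         paste(nm[is.na(assignment)], collapse = ", "), call. = FALSE)
  }
  assignment <- as.integer(assignment)
  names(assignment) <- nm
  if (anyDuplicated(assignment)) {
    stop("Assignment maps two factors to the same column", call. = FALSE)
  }
  if (any(assignment < 1L | assignment > array$columns)) {
    stop("Assignment has column indices outside 1..", array$columns,
         call. = FALSE)
  }
  for (f in factors) {
    col <- assignment[[f$name]]
    if (length(f$levels) != array$levels_per_col[col]) {
      stop("Factor '", f$name, "' has ", length(f$levels),
           " levels but column ", col, " of ", array$id, " has ",
           array$levels_per_col[col], call. = FALSE)
    }
  }

  design <- data.frame(run = seq_len(array$runs))
  for (f in factors) {
    idx <- array$matrix[, assignment[[f$name]]]
    design[[f$name]] <- f$levels[idx]
  }
  structure(
    list(
      array = array,
      factors = factors,
      assignment = assignment,
      design = design,
      unused_columns = setdiff(seq_len(array$columns), assignment)
    ),
    class = "tsto_plan"
  )
}

#' Level index of each run for one factor of a plan
#' @param plan A `tsto_plan`.
#' @param name Factor name.
#' @return Integer vector (one 1-based level index per run).
#' @keywords internal
plan_level_index <- function(plan, name) {
  plan$array$matrix[, plan$assignment[[name]]]
}

#' Write / read a realized experiment plan as CSV
#'
#' The CSV has a `run` column followed by one column per factor holding the
#' realized values (numeric at full precision, categorical as labels).
#' `read_plan_csv()` re-reads such a file; with the originating `factors`
#' list the typed design round-trips exactly.
#'
#' @param plan A `tsto_plan`.
#' @param path File path.
#' @return `write_plan_csv()`: the path, invisibly. `read_plan_csv()`: a
#'   data frame with `run` plus factor columns.
#' @export
write_plan_csv <- function(plan, path) {
  utils::write.csv(plan$design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plan_csv
#' @param factors Optional factor list used to restore column types.
#' @export
read_plan_csv <- function(path, factors = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"run" %in% names(df)) stop("Plan CSV must have a 'run' column", call. = FALSE)
  if (!is.null(factors)) {
    factors <- .check_factor_list(factors)
    for (f in factors) {
      if (!f$name %in% names(df)) {
        stop("Plan CSV is missing factor column '", f$name, "'", call. = FALSE)
      }
      df[[f$name]] <- if (f$role == "categorical") as.character(df[[f$name]])
                      else as.numeric(df[[f$name]])
    }
  }
  df
}

#' @export
print.tsto_plan <- function(x, ...) {
  cat(sprintf("Experiment plan on %s: %d runs, %d factors (columns %s)\n",
              x$array$id, x$array$runs, length(x$factors),
              paste(x$assignment, collapse = ", ")))
  if (length(x$unused_columns)) {
    cat("  unused columns:", paste(x$unused_columns, collapse = ", "), "\n")
  }
  print(x$design, row.names = FALSE)
  invisible(x)
}
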