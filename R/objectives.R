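# Objective contract and concrete objectives.
#
# An objective is a function `f(assignment, replicate, seed)` returning a
# response in (0, 1], deterministic given its three arguments:
#   assignment - named list, factor name -> level value
#   replicate  - 1-based replicate index
#   seed       - integer seed for any stochastic component
# Objectives are tagged with class "tsto_objective"; metadata (e.g. the
# known optimum of a synthetic objective) lives in attributes.

.as_objective <- function(fn, ...) {
  stopifnot(is.function(fn))
  attrs <- list(...)
  for (nm in names(attrs)) attr(fn, nm) <- attrs[[nm]]
  class(fn) <- c("tsto_objective", class(fn))
  fn
}

.assignment_key <- function(assignment) {
  ord <- order(names(assignment))
  vals <- vapply(assignment[ord], function(v) {
    if (is.numeric(v)) format(v, digits = 15) else as.character(v)
  }, "")
  paste(names(assignment)[ord], vals, sep = "=", collapse = "|")
}

#' Replay objective: look up printed/recorded responses
#'
#' Wraps a table of already-measured responses (e.g. the bundled worked
#' example) as an objective, so the full two-stage driver can be replayed
#' over recorded data without re-running any model training. The lookup is
#' a total function over its declared design: each (run setting, replicate)
#' must be present.
#'
#' @param plan The `tsto_plan` the responses were measured on.
#' @param results Data frame `run, rep_1, ..., rep_k` (wide) or
#'   `run, rep, response` (long).
#' @return A `tsto_objective` function.
#' @examples
#' ex <- cvd_example_stage2()
#' obj <- lookup_objective(ex$plan, ex$results)
#' obj(as.list(ex$plan$design[1, -1]), replicate = 1, seed = 0)  # 0.7390
#' @export
lookup_objective <- function(plan, results) {
  stopifnot(inherits(plan, "tsto_plan"), is.data.frame(results))
  if (all(c("run", "rep", "response") %in% names(results))) {
    long <- results
  } else {
    rep_cols <- grep("^rep_", names(results), value = TRUE)
    stopifnot("run" %in% names(results), length(rep_cols) >= 1L)
    long <- do.call(rbind, lapply(seq_along(rep_cols), function(k) {
      data.frame(run = results$run, rep = k,
                 response = results[[rep_cols[k]]])
    }))
  }
  fnames <- names(plan$factors)
  table <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(long))) {
    row <- plan$design[plan$design$run == long$run[i], fnames, drop = FALSE]
    key <- paste(.assignment_key(as.list(row)), long$rep[i], sep = "#")
    assign(key, long$response[i], envir = table)
  }
  .as_objective(function(assignment, replicate, seed) {
    key <- paste(.assignment_key(assignment[fnames]), replicate, sep = "#")
    if (!exists(key, envir = table, inherits = FALSE)) {
      stop("Lookup objective has no recorded response for setting [",
           .assignment_key(assignment[fnames]), "] replicate ", replicate,
           call. = FALSE)
    }
    get(key, envir = table, inherits = FALSE)
  }, type = "lookup")
}

#' Replay objective for a fixed sequence of confirmation responses
#'
#' Returns the `replicate`-th value of `values` regardless of the setting;
#' used to replay recorded confirmation experiments.
#'
#' @param values Numeric responses, indexed by replicate.
#' @return A `tsto_objective` function.
#' @export
replay_objective <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  .as_objective(function(assignment, replicate, seed) {
    if (replicate > length(values)) {
      stop("Replay objective has only ", length(values), " recorded values",
           call. = FALSE)
    }
    values[[replicate]]
  }, type = "replay")
}

#' Synthetic additive objective with a known optimum
#'
#' Test harness for the design-of-experiments machinery: the response at a
#' setting is `baseline + sum(effects[[f]][level(f)]) + N(0, sigma^2)`,
#' clipped to (1e-6, 1]. With `sigma = 0` the response is exactly additive,
#' so the pipeline must recover every level mean and the true optimum
#' exactly; with noise it emulates the replicate-to-replicate training
#' variation of a real model. The true optimum (per-factor argmax of the
#' additive effects, unique by construction) is stored in attributes
#' `true_best` and `true_optimum`.
#'
#' For numeric factors the effect is interpolated linearly between the
#' declared level values (and held constant beyond them), so the objective
#' remains defined at refined off-grid settings such as the midpoints a
#' second stage explores; categorical factors require an exact level
#' match.
#'
#' Default effects mirror the worked example's structure: two dominant
#' factors (effect about 0.16, with a clearly best middle level) and the
#' rest minor (about 0.04), over a baseline of 0.5 — the regime in which
#' a screening design must separate important from unimportant
#' hyperparameters.
#'
#' @param factors List of [factor_spec()] objects.
#' @param baseline Baseline response (default 0.5).
#' @param effects Named list: factor name -> numeric vector of per-level
#'   additive effects (same length as the factor's levels). Default: the
#'   first two factors get `c(0, 0.16, 0.08)` (truncated to the level
#'   count), the rest `c(0, 0.02, 0.04)`.
#' @param sigma Gaussian noise SD (default 0).
#' @return A `tsto_objective` with attributes `true_best` (named list of
#'   optimal level values) and `true_optimum` (noise-free response there).
#' @examples
#' f <- list(factor_spec("a", 1:3, role = "integer"),
#'           factor_spec("b", 1:3, role = "integer"))
#' obj <- synthetic_additive_objective(f)
#' attr(obj, "true_best")
#' @export
synthetic_additive_objective <- function(factors, baseline = 0.5,
                                         effects = NULL, sigma = 0) {
  factors <- .check_factor_list(factors)
  stopifnot(sigma >= 0)
  if (is.null(effects)) {
    effects <- list()
    for (i in seq_along(factors)) {
      pat <- if (i <= 2) c(0, 0.16, 0.08) else c(0, 0.02, 0.04)
      effects[[names(factors)[i]]] <- pat[seq_along(factors[[i]]$levels)]
    }
  }
  for (f in factors) {
    e <- effects[[f$name]]
    if (is.null(e) || length(e) != length(f$levels)) {
      stop("Effects for factor '", f$name, "' must have one value per level",
           call. = FALSE)
    }
    if (sum(e == max(e)) != 1L) {
      stop("Effects for factor '", f$name,
           "' must have a unique maximum (unique optimum by construction)",
           call. = FALSE)
    }
  }
  true_best <- lapply(factors, function(f) f$levels[which.max(effects[[f$name]])])
  true_optimum <- baseline + sum(vapply(effects, max, numeric(1)))
  if (true_optimum > 1 || baseline <= 0) {
    stop("baseline + maximal effects must lie in (0, 1]", call. = FALSE)
  }

  .as_objective(function(assignment, replicate, seed) {
    y <- baseline
    for (f in factors) {
      val <- assignment[[f$name]]
      if (is.null(val)) stop("Assignment missing factor '", f$name, "'",
                             call. = FALSE)
      if (f$role == "categorical") {
        lev <- match(as.character(val), f$levels)
        if (is.na(lev)) {
          stop("Assignment value '", val, "' is not a declared level of '",
               f$name, "'", call. = FALSE)
        }
        y <- y + effects[[f$name]][lev]
      } else {
        y <- y + stats::approx(f$levels, effects[[f$name]],
                               xout = as.numeric(val), rule = 2)$y
      }
    }
    if (sigma > 0) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      y <- y + stats::rnorm(1, sd = sigma)
    }
    min(max(y, 1e-6), 1)
  },
  type = "synthetic_additive", true_best = true_best,
  true_optimum = true_optimum, sigma = sigma, effects = effects,
  baseline = baseline)
}
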