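# Signal-to-noise ratios (decibel scale) and replicate summarization.

#' Taguchi signal-to-noise ratios
#'
#' Decibel-scale quality statistics over the replicate responses of one
#' experimental run:
#' \describe{
#'   \item{larger-the-better}{`-10*log10(mean(1/y^2))` — rewards large
#'     responses; all values must be positive. Used for accuracies.}
#'   \item{smaller-the-better}{`-10*log10(mean(y^2))` — penalizes
#'     magnitude; the ideal response is 0.}
#'   \item{nominal-the-better}{`-10*log10(mean((y - m)^2))` — penalizes
#'     deviation from a target `m`.}
#' }
#' When the mean-square term is exactly zero (an ideal response) the SN is
#' `Inf` by convention rather than an error.
#'
#' @param values Numeric replicate responses of one run.
#' @param m Target value (nominal-the-better only).
#' @return SN ratio in dB.
#' @examples
#' sn_larger_the_better(c(0.4951, 0.4951, 0.4951))  # -6.105 dB
#' sn_smaller_the_better(c(0.5, 0.5))               # +6.02 dB
#' sn_nominal_the_better(c(2, 4), m = 3)            # 0 dB
#' @export
sn_larger_the_better <- function(values) {
  if (length(values) == 0L) stop("Empty replicate vector", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("Larger-the-better SN requires strictly positive responses",
         call. = FALSE)
  }
  -10 * log10(mean(1 / values^2))
}

#' @rdname sn_larger_the_better
#' @export
sn_smaller_the_better <- function(values) {
  if (length(values) == 0L) stop("Empty replicate vector", call. = FALSE)
  msq <- mean(values^2)
  if (msq == 0) return(Inf)  # ideal: all responses exactly zero
  -10 * log10(msq)
}

#' @rdname sn_larger_the_better
#' @export
sn_nominal_the_better <- function(values, m) {
  if (length(values) == 0L) stop("Empty replicate vector", call. = FALSE)
  stopifnot(is.numeric(m), length(m) == 1L)
  msd <- mean((values - m)^2)
  if (msd == 0) return(Inf)  # ideal: on target everywhere
  -10 * log10(msd)
}

.sn_fun <- function(sn_type, m = NULL) {
  switch(sn_type,
    ltb = sn_larger_the_better,
    stb = sn_smaller_the_better,
    ntb = function(values) sn_nominal_the_better(values, m),
    stop("Unknown SN type '", sn_type, "'", call. = FALSE)
  )
}

#' Summarize replicated run results: mean, sample SD and SN ratio
#'
#' Produces the per-run summary table of a replicated design: the mean,
#' the sample standard deviation (denominator n-1) and the SN ratio of
#' each run's replicates, plus grand values over runs. The grand SD column
#' is the mean of the per-run sample SDs (not a pooled SD).
#'
#' @param plan A `tsto_plan`.
#' @param results Data frame with a `run` column and one `rep_*` column per
#'   replicate (any non-`run` columns are taken as replicates, in order).
#' @param sn_type `"ltb"`, `"stb"` or `"ntb"`.
#' @param m Target value when `sn_type = "ntb"`.
#' @return A `tsto_summary` object: data frame `run`, factor values,
#'   `mean`, `sd`, `sn`, with attributes `grand_mean`, `grand_sd`,
#'   `grand_sn` and `replicates` (the replicate matrix).
#' @examples
#' ex <- cvd_example_stage2()
#' s <- summarize_runs(ex$plan, ex$results)
#' attr(s, "grand_mean")  # 0.7378
#' @export
summarize_runs <- function(plan, results, sn_type = c("ltb", "stb", "ntb"),
                           m = NULL) {
  sn_type <- match.arg(sn_type)
  stopifnot(inherits(plan, "tsto_plan"), is.data.frame(results))
  if (!"run" %in% names(results)) {
    stop("Results must have a 'run' column", call. = FALSE)
  }
  missing_runs <- setdiff(plan$design$run, results$run)
  if (length(missing_runs)) {
    stop("No results for run(s): ", paste(missing_runs, collapse = ", "),
         call. = FALSE)
  }
  results <- results[match(plan$design$run, results$run), , drop = FALSE]
  rep_cols <- setdiff(names(results), "run")
  if (!length(rep_cols)) stop("Results contain no replicate columns", call. = FALSE)
  reps <- as.matrix(results[rep_cols])
  if (!is.numeric(reps) || anyNA(reps)) {
    stop("Replicate responses must be numeric and complete", call. = FALSE)
  }

  snf <- .sn_fun(sn_type, m)
  run_mean <- rowMeans(reps)
  run_sd <- if (ncol(reps) >= 2L) apply(reps, 1L, stats::sd) else rep(0, nrow(reps))
  run_sn <- apply(reps, 1L, snf)

  out <- cbind(plan$design, mean = run_mean, sd = run_sd, sn = run_sn)
  structure(out,
            class = c("tsto_summary", "data.frame"),
            grand_mean = mean(run_mean),
            grand_sd = mean(run_sd),
            grand_sn = mean(run_sn),
            sn_type = sn_type,
            replicates = reps)
}

#' @export
print.tsto_summary <- function(x, digits_mean = 4, digits_sn = 3, ...) {
  df <- as.data.frame(x)
  df$mean <- round(df$mean, digits_mean)
  df$sd <- round(df$sd, digits_mean)
  df$sn <- round(df$sn, digits_sn)
  print(df, row.names = FALSE)
  cat(sprintf("Grand: mean %.4f  sd %.4f  SN %.3f dB\n",
              attr(x, "grand_mean"), attr(x, "grand_sd"), attr(x, "grand_sn")))
  invisible(x)
}
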