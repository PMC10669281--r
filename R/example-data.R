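# Bundled worked example: replicated test accuracies of a multilayer
# perceptron predicting cardiovascular-disease risk on the Kaggle CVD
# dataset, measured over an L18(2^1 x 3^7) screening design (six
# hyperparameters on columns 2-7, three training replicates per run) and
# an L9(3^4) refinement design around the screening winner. The raw
# replicate accuracies, the two five-run confirmation experiments and the
# factor level tables are stored verbatim so the entire analysis chain
# (response tables, pooled ANOVA, additive predictions, confirmation
# intervals) can be recomputed without retraining any network.

#' Worked example: hyperparameter screening and refinement data
#'
#' `cvd_example_stage1()` returns the coarse screening stage: six MLP
#' hyperparameters (hidden layers, activation, optimizer, learning rate,
#' momentum rate, hidden nodes) on columns 2-7 of L18(2^1 x 3^7) with
#' three replicate test accuracies per run, plus the five confirmation
#' accuracies measured at the recommended setting.
#' `cvd_example_stage2()` returns the refinement stage: the three numeric
#' factors re-leveled around the stage-1 winner (learning rate
#' 0.3±0.05, momentum 0.9±0.05, hidden nodes 8±2) on columns 1-3 of
#' L9(3^4), with its confirmation accuracies.
#'
#' @return A list with `factors` (list of [factor_spec()]), `plan`
#'   (`tsto_plan`), `results` (data frame `run`, `rep_1..rep_3`) and
#'   `confirmation` (numeric vector of 5 accuracies).
#' @examples
#' ex <- cvd_example_stage1()
#' summarize_runs(ex$plan, ex$results)
#' @export
cvd_example_stage1 <- function() {
  factors <- list(
    factor_spec("hidden_layers", c(4, 8, 12), role = "integer",
                structural = TRUE, lower = 1),
    factor_spec("activation", c("logistic", "tanh", "relu")),
    factor_spec("optimizer", c("lbfgs", "sgd", "adam")),
    factor_spec("learning_rate", c(0.2, 0.3, 0.4), role = "numeric",
                lower = 1e-6, upper = 1),
    factor_spec("moment_rate", c(0.7, 0.8, 0.9), role = "numeric",
                lower = 1e-6, upper = 1),
    factor_spec("hidden_nodes", c(4, 8, 12), role = "integer", lower = 1)
  )
  plan <- make_plan(factors, "L18_2^1x3^7",
                    assignment = c(hidden_layers = 2, activation = 3,
                                   optimizer = 4, learning_rate = 5,
                                   moment_rate = 6, hidden_nodes = 7))
  acc <- matrix(c(
    0.4951, 0.4951, 0.4951,
    0.7389, 0.7382, 0.7262,
    0.4951, 0.5049, 0.4951,
    0.4951, 0.4951, 0.4951,
    0.7404, 0.7405, 0.7331,
    0.4951, 0.4951, 0.4951,
    0.4951, 0.5049, 0.5049,
    0.4951, 0.4951, 0.5136,
    0.7341, 0.7414, 0.4951,
    0.4951, 0.4951, 0.4951,
    0.7361, 0.7386, 0.7372,
    0.7389, 0.7381, 0.7404,
    0.5049, 0.4951, 0.4951,
    0.4951, 0.5049, 0.4951,
    0.7416, 0.7412, 0.7404,
    0.4951, 0.4951, 0.4951,
    0.7441, 0.7418, 0.7423,
    0.7384, 0.7240, 0.7431
  ), ncol = 3, byrow = TRUE)
  results <- data.frame(run = 1:18, rep_1 = acc[, 1], rep_2 = acc[, 2],
                        rep_3 = acc[, 3])
  confirmation <- c(0.7398, 0.7392, 0.7394, 0.7369, 0.7361)
  list(factors = factors, plan = plan, results = results,
       confirmation = confirmation)
}

#' @rdname cvd_example_stage1
#' @export
cvd_example_stage2 <- function() {
  factors <- list(
    factor_spec("learning_rate", c(0.25, 0.30, 0.35), role = "numeric",
                lower = 1e-6, upper = 1),
    factor_spec("moment_rate", c(0.85, 0.90, 0.95), role = "numeric",
                lower = 1e-6, upper = 1),
    factor_spec("hidden_nodes", c(6, 8, 10), role = "integer", lower = 1)
  )
  plan <- make_plan(factors, "L9_3^4",
                    assignment = c(learning_rate = 1, moment_rate = 2,
                                   hidden_nodes = 3))
  acc <- matrix(c(
    0.7390, 0.7379, 0.7417,
    0.7392, 0.7381, 0.7376,
    0.7348, 0.7414, 0.7398,
    0.7348, 0.7411, 0.7399,
    0.7399, 0.7341, 0.7400,
    0.7357, 0.7360, 0.7395,
    0.7418, 0.7349, 0.7388,
    0.7376, 0.7301, 0.7374,
    0.7420, 0.7374, 0.7291
  ), ncol = 3, byrow = TRUE)
  results <- data.frame(run = 1:9, rep_1 = acc[, 1], rep_2 = acc[, 2],
                        rep_3 = acc[, 3])
  confirmation <- c(0.7401, 0.7410, 0.7439, 0.7415, 0.7407)
  list(factors = factors, plan = plan, results = results,
       confirmation = confirmation)
}

#' Write the worked-example tables as replayable CSV fixtures
#'
#' Emits the screening and refinement designs with their raw replicate
#' accuracies and the two confirmation experiments as plain CSV files:
#' `stage1_design_results.csv` (18 rows: run, 6 factor columns, 3
#' replicate columns), `stage2_design_results.csv` (9 rows: run, 3 factor
#' columns, 3 replicate columns), `stage1_confirmation.csv` and
#' `stage2_confirmation.csv` (5 values each), plus lookup-objective files
#' `stage1_lookup.csv` / `stage2_lookup.csv` in `run,rep,response` form.
#'
#' @param dir Output directory (created if absent).
#' @return Invisibly, the character vector of files written.
#' @export
generate_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    files <<- c(files, path)
  }
  for (stage in c("stage1", "stage2")) {
    ex <- if (stage == "stage1") cvd_example_stage1() else cvd_example_stage2()
    emit(merge(ex$plan$design, ex$results, by = "run"),
         paste0(stage, "_design_results.csv"))
    emit(data.frame(rep = seq_along(ex$confirmation),
                    response = ex$confirmation),
         paste0(stage, "_confirmation.csv"))
    long <- do.call(rbind, lapply(1:3, function(k) {
      data.frame(run = ex$results$run, rep = k,
                 response = ex$results[[paste0("rep_", k)]])
    }))
    emit(long[order(long$run, long$rep), ], paste0(stage, "_lookup.csv"))
  }
  invisible(files)
}
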