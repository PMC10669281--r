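# Two-stage Taguchi optimization driver: screening stage, confirmation,
# refinement of numeric factors around the winner, refinement stage.

.eval_seed <- function(seed, run, replicate) {
  # deterministic per-evaluation seed, kept inside 32-bit integer range
  as.integer((as.numeric(seed) * 100003 + run * 1009 + replicate) %% 2147483629)
}

.select_array <- function(factors) {
  for (id in oa_list()) {
    ok <- tryCatch({
      make_plan(factors, id)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(id)
  }
  stop("No catalog array accommodates ", length(factors), " factor(s) with ",
       "levels ", paste(vapply(factors, function(f) length(f$levels), 0L),
                        collapse = "/"), call. = FALSE)
}

#' Configuration of one Taguchi stage
#'
#' @param factors List of [factor_spec()] objects.
#' @param array Array identifier, or `NULL` to pick the smallest catalog
#'   array that accommodates the factors.
#' @param assignment Named factor -> column map, or `NULL` for the default
#'   greedy assignment.
#' @param replicates Replicate evaluations per run (default 3).
#' @param sn_type SN ratio type (default `"ltb"`; accuracies are
#'   larger-the-better).
#' @param screen_alpha Significance level for factor screening
#'   (default 0.1).
#' @param ci_alpha Significance level for confirmation intervals
#'   (default 0.05).
#' @param retain_k Pooling rule: keep the `retain_k` largest-SS factors
#'   and pool the rest into the error term (default 2).
#' @param pooled Explicit pooled factor set overriding `retain_k`
#'   (`NULL` = use the rule).
#' @param r Number of confirmation runs (default 5).
#' @param seed Integer seed; every evaluation derives its own seed from
#'   (seed, run, replicate).
#' @return A `tsto_config` list.
#' @export
stage_config <- function(factors, array = NULL, assignment = NULL,
                         replicates = 3, sn_type = "ltb",
                         screen_alpha = 0.1, ci_alpha = 0.05,
                         retain_k = 2, pooled = NULL, r = 5, seed = 1) {
  factors <- .check_factor_list(factors)
  stopifnot(replicates >= 1, r >= 1, retain_k >= 1,
            screen_alpha > 0, screen_alpha < 1, ci_alpha > 0, ci_alpha < 1)
  if (is.null(array)) array <- .select_array(factors)
  structure(
    list(factors = factors, array = array, assignment = assignment,
         replicates = as.integer(replicates), sn_type = sn_type,
         screen_alpha = screen_alpha, ci_alpha = ci_alpha,
         retain_k = as.integer(retain_k), pooled = pooled,
         r = as.integer(r), seed = as.integer(seed)),
    class = "tsto_config"
  )
}

.pooled_set <- function(plan, response, retain_k, pooled, kind) {
  if (!is.null(pooled)) return(pooled)
  nm <- names(plan$factors)
  if (retain_k >= length(nm)) return(character(0))
  # rank factors by their sum of squares on this response (computed
  # directly: the full-model ANOVA may have no error DF on a saturated
  # design, which is irrelevant for ranking)
  y <- .per_run_response(plan, response, kind)
  grand <- mean(y)
  ss <- vapply(plan$factors, function(f) {
    idx <- plan_level_index(plan, f$name)
    nlev <- length(f$levels)
    lm <- vapply(seq_len(nlev), function(l) mean(y[idx == l]), numeric(1))
    (length(y) / nlev) * sum((lm - grand)^2)
  }, numeric(1))
  keep <- names(sort(ss, decreasing = TRUE))[seq_len(retain_k)]
  setdiff(nm, keep)
}

#' Execute one Taguchi stage: design, evaluate, analyze
#'
#' Realizes the plan, evaluates the objective for every run and replicate
#' (with per-evaluation seeds derived from the stage seed), then runs the
#' whole analysis chain: replicate summary, mean and SN response tables,
#' pooled ANOVA for both responses (retain-top-k pooling unless an
#' explicit pooled set is configured), best levels, significant factors,
#' additive predictions at the best setting using the retained factors,
#' and confirmation confidence half-widths.
#'
#' @param config A [stage_config()].
#' @param objective A `tsto_objective` (see [lookup_objective()],
#'   [synthetic_additive_objective()], [mlp_objective()]).
#' @return A `tsto_stage` list: `plan`, `results`, `summary`, `rt_mean`,
#'   `rt_sn`, `anova_mean`, `anova_sn`, `retained_mean`, `retained_sn`,
#'   `significant_mean`, `significant_sn`, `best`, `pred_mean`, `pred_sn`,
#'   `ci_mean`, `ci_sn`, `eval_log`, `config`.
#' @examples
#' ex <- cvd_example_stage2()
#' cfg <- stage_config(ex$factors, array = "L9",
#'                     assignment = c(learning_rate = 1, moment_rate = 2,
#'                                    hidden_nodes = 3))
#' st <- run_stage(cfg, lookup_objective(ex$plan, ex$results))
#' st$pred_mean$predicted  # 0.7399
#' @export
run_stage <- function(config, objective) {
  stopifnot(inherits(config, "tsto_config"), is.function(objective))
  plan <- make_plan(config$factors, config$array, config$assignment)
  fnames <- names(plan$factors)

  log <- vector("list", plan$array$runs * config$replicates)
  reps <- matrix(NA_real_, plan$array$runs, config$replicates)
  k <- 0L
  for (run in plan$design$run) {
    assignment <- as.list(plan$design[plan$design$run == run, fnames,
                                      drop = FALSE])
    for (repl in seq_len(config$replicates)) {
      s <- .eval_seed(config$seed, run, repl)
      y <- tryCatch(objective(assignment, repl, s), error = function(e) {
        stop("Objective failed on run ", run, " replicate ", repl, ": ",
             conditionMessage(e), call. = FALSE)
      })
      reps[run, repl] <- y
      k <- k + 1L
      log[[k]] <- data.frame(run = run, replicate = repl, seed = s,
                             response = y,
                             setting = .assignment_key(assignment))
    }
  }
  results <- data.frame(run = plan$design$run)
  for (j in seq_len(config$replicates)) results[[paste0("rep_", j)]] <- reps[, j]

  summary <- summarize_runs(plan, results, sn_type = config$sn_type)
  rt_mean <- response_table(plan, summary, kind = "mean")
  rt_sn <- response_table(plan, summary, kind = "sn")

  pooled_mean <- .pooled_set(plan, summary, config$retain_k, config$pooled, "mean")
  pooled_sn <- .pooled_set(plan, summary, config$retain_k, config$pooled, "sn")
  anova_mean <- taguchi_anova(plan, summary, pooled = pooled_mean, kind = "mean")
  anova_sn <- taguchi_anova(plan, summary, pooled = pooled_sn, kind = "sn")
  retained_mean <- setdiff(fnames, pooled_mean)
  retained_sn <- setdiff(fnames, pooled_sn)

  best <- select_best_levels(rt_mean, rt_sn)
  pred_mean <- predict_additive(rt_mean, best[retained_mean])
  pred_sn <- predict_additive(rt_sn, best[retained_sn])
  ci_mean <- confidence_halfwidth(anova_mean, plan$array$runs, retained_mean,
                                  r = config$r, alpha = config$ci_alpha,
                                  center = pred_mean$predicted)
  ci_sn <- confidence_halfwidth(anova_sn, plan$array$runs, retained_sn,
                                r = config$r, alpha = config$ci_alpha,
                                center = pred_sn$predicted)

  structure(
    list(plan = plan, results = results, summary = summary,
         rt_mean = rt_mean, rt_sn = rt_sn,
         anova_mean = anova_mean, anova_sn = anova_sn,
         retained_mean = retained_mean, retained_sn = retained_sn,
         significant_mean = significant_factors(anova_mean, config$screen_alpha),
         significant_sn = significant_factors(anova_sn, config$screen_alpha),
         best = best, pred_mean = pred_mean, pred_sn = pred_sn,
         ci_mean = ci_mean, ci_sn = ci_sn,
         eval_log = do.call(rbind, log), config = config),
    class = "tsto_stage"
  )
}

#' Refine numeric factors around a stage-1 winner
#'
#' Builds the stage-2 factor list: categorical factors are fixed at their
#' stage-1 best level; a structural factor whose best level is the
#' smallest is fixed (shrinking capacity further risks degrading the
#' model); every other numeric factor is re-leveled to
#' `{best - step, best, best + step}` with `step = (stage-1 level
#' spacing)/2` (integer factors: step rounded to the nearest positive
#' integer). Refined levels may extend beyond the stage-1 range; they are
#' clipped to the factor's declared bounds with a warning.
#'
#' @param stage1 A `tsto_stage` from the screening stage.
#' @return A `tsto_refinement`: list with `factors` (refined
#'   [factor_spec()] list), `fixed` (named list of fixed factor values)
#'   and `rule` (data frame of center/step per refined factor).
#' @examples
#' ex <- cvd_example_stage1()
#' cfg <- stage_config(ex$factors, array = "L18",
#'                     assignment = c(hidden_layers = 2, activation = 3,
#'                                    optimizer = 4, learning_rate = 5,
#'                                    moment_rate = 6, hidden_nodes = 7))
#' st1 <- run_stage(cfg, lookup_objective(ex$plan, ex$results))
#' refine_factors(st1)$rule
#' @export
refine_factors <- function(stage1) {
  stopifnot(inherits(stage1, "tsto_stage"))
  refined <- list()
  fixed <- list()
  rule <- list()
  for (f in stage1$plan$factors) {
    best <- stage1$best[[f$name]]
    if (f$role == "categorical") {
      fixed[[f$name]] <- best
      next
    }
    if (f$structural && isTRUE(best == min(f$levels))) {
      fixed[[f$name]] <- best
      next
    }
    spacing <- mean(diff(f$levels))
    step <- spacing / 2
    if (f$role == "integer") {
      step <- round(step)
      if (step < 1) {
        stop("Refinement step for integer factor '", f$name,
             "' rounds to zero", call. = FALSE)
      }
    }
    lv <- c(best - step, best, best + step)
    clipped <- pmin(pmax(lv, f$lower), f$upper)
    if (!identical(clipped, lv)) {
      warning("Refined levels of '", f$name, "' clipped to [",
              f$lower, ", ", f$upper, "]", call. = FALSE)
      lv <- clipped
    }
    if (any(diff(lv) <= 0)) {
      stop("Refined levels of '", f$name,
           "' are not strictly increasing after clipping", call. = FALSE)
    }
    refined[[f$name]] <- factor_spec(f$name, lv, role = f$role,
                                     structural = f$structural,
                                     lower = f$lower, upper = f$upper)
    rule[[f$name]] <- data.frame(factor = f$name, center = best, step = step)
  }
  if (!length(refined)) {
    stop("No numeric factor left to refine", call. = FALSE)
  }
  structure(list(factors = refined, fixed = fixed,
                 rule = do.call(rbind, rule)),
            class = "tsto_refinement")
}

#' Confirmation experiment at a chosen setting
#'
#' Runs `r` fresh evaluations at `setting`, summarizes them (mean, sample
#' SD, SN ratio) and flags whether the observed mean and SN fall inside
#' the predicted value plus/minus the confidence half-width. Confirmation
#' is advisory: a failed flag is reported, never an error.
#'
#' @param setting Named list: factor -> level value.
#' @param objective A `tsto_objective`.
#' @param r Number of confirmation evaluations.
#' @param ci_mean,ci_sn `tsto_ci` objects carrying `center` (the additive
#'   predictions); either may be `NULL` to skip that check.
#' @param sn_type SN ratio type (default `"ltb"`).
#' @param seed Integer seed (replicates use seeds derived from it).
#' @return A `tsto_confirmation`: list with `values`, `mean`, `sd`, `sn`,
#'   `pass_mean`, `pass_sn`, `ci_mean`, `ci_sn`, `setting`.
#' @export
confirm_setting <- function(setting, objective, r = 5,
                            ci_mean = NULL, ci_sn = NULL,
                            sn_type = "ltb", seed = 1) {
  stopifnot(r >= 1, is.function(objective))
  vals <- vapply(seq_len(r), function(k) {
    objective(setting, k, .eval_seed(seed, 0L, k))
  }, numeric(1))
  m <- mean(vals)
  s <- if (r >= 2) stats::sd(vals) else 0
  sn <- .sn_fun(sn_type)(vals)
  inside <- function(obs, ci) {
    if (is.null(ci) || is.null(ci$center)) return(NA)
    abs(obs - ci$center) <= ci$halfwidth
  }
  structure(
    list(values = vals, mean = m, sd = s, sn = sn,
         pass_mean = inside(m, ci_mean), pass_sn = inside(sn, ci_sn),
         ci_mean = ci_mean, ci_sn = ci_sn, setting = setting),
    class = "tsto_confirmation"
  )
}

#' Run the full two-stage Taguchi optimization
#'
#' Stage 1 screens all factors on a coarse array and validates the
#' recommended setting with `r` confirmation runs; the numeric factors are
#' then refined around the winner with halved level spacing ([refine_factors()])
#' and stage 2 re-optimizes them on a smaller array (L9 when exactly three
#' 3-level factors advance; otherwise the smallest catalog array that
#' fits, with a warning), followed by its own confirmation. The report
#' ends with a comparison table (stage settings, confirmation mean, SD,
#' SN, and an improvement row of stage-2 minus stage-1 differences).
#'
#' @param config Stage-1 [stage_config()].
#' @param objective Stage-1 objective.
#' @param stage2_objective Objective for stage 2 (default: `objective`).
#'   It receives the full assignment, fixed factors included.
#' @param confirm1_objective,confirm2_objective Objectives for the two
#'   confirmation experiments (defaults: the respective stage objectives).
#' @return A `tsto_report`: list with `stage1`, `confirm1`, `refinement`,
#'   `stage2`, `confirm2`, `best_setting`, `comparison` (data frame in the
#'   comparison-table shape) and `budget` (stage-wise experiment budgets).
#' @examples
#' ex1 <- cvd_example_stage1(); ex2 <- cvd_example_stage2()
#' cfg <- stage_config(ex1$factors, array = "L18",
#'                     assignment = c(hidden_layers = 2, activation = 3,
#'                                    optimizer = 4, learning_rate = 5,
#'                                    moment_rate = 6, hidden_nodes = 7))
#' rep <- run_tsto(cfg, lookup_objective(ex1$plan, ex1$results),
#'                 stage2_objective = lookup_objective(ex2$plan, ex2$results),
#'                 confirm1_objective = replay_objective(ex1$confirmation),
#'                 confirm2_objective = replay_objective(ex2$confirmation))
#' rep$comparison
#' @export
run_tsto <- function(config, objective, stage2_objective = objective,
                     confirm1_objective = objective,
                     confirm2_objective = stage2_objective) {
  stage1 <- run_stage(config, objective)
  confirm1 <- confirm_setting(stage1$best, confirm1_objective, r = config$r,
                              ci_mean = stage1$ci_mean, ci_sn = stage1$ci_sn,
                              sn_type = config$sn_type,
                              seed = config$seed + 1L)

  ref <- refine_factors(stage1)
  n3 <- sum(vapply(ref$factors, function(f) length(f$levels) == 3L, logical(1)))
  array2 <- if (n3 == 3L && length(ref$factors) == 3L) {
    "L9_3^4"
  } else {
    id <- .select_array(ref$factors)
    warning("Stage 2 has ", length(ref$factors),
            " refined factor(s); selected array ", id, call. = FALSE)
    id
  }
  config2 <- stage_config(ref$factors, array = array2,
                          replicates = config$replicates,
                          sn_type = config$sn_type,
                          screen_alpha = config$screen_alpha,
                          ci_alpha = config$ci_alpha,
                          retain_k = config$retain_k, r = config$r,
                          seed = config$seed + 2L)
  obj2 <- function(assignment, replicate, seed) {
    stage2_objective(c(ref$fixed, assignment), replicate, seed)
  }
  stage2 <- run_stage(config2, obj2)
  best_setting <- c(ref$fixed, stage2$best)[names(config$factors)]
  confirm2 <- confirm_setting(best_setting, confirm2_objective, r = config$r,
                              ci_mean = stage2$ci_mean, ci_sn = stage2$ci_sn,
                              sn_type = config$sn_type,
                              seed = config$seed + 3L)

  setting_row <- function(setting) {
    as.data.frame(lapply(setting, function(v) if (is.numeric(v)) v else as.character(v)),
                  stringsAsFactors = FALSE)
  }
  s1 <- c(stage1$best)[names(config$factors)]
  comparison <- cbind(
    stage = c(stage1$plan$array$id, stage2$plan$array$id, "Improvement"),
    rbind(setting_row(s1), setting_row(best_setting),
          stats::setNames(as.data.frame(as.list(rep(NA, length(s1)))), names(s1))),
    mean = c(confirm1$mean, confirm2$mean, confirm2$mean - confirm1$mean),
    sd = c(confirm1$sd, confirm2$sd, confirm2$sd - confirm1$sd),
    sn = c(confirm1$sn, confirm2$sn, confirm2$sn - confirm1$sn)
  )
  budget <- rbind(
    cbind(stage = "stage1",
          as.data.frame(experiment_budget(config$factors, config$replicates,
                                          stage1$plan$array))),
    cbind(stage = "stage2",
          as.data.frame(experiment_budget(config2$factors, config2$replicates,
                                          stage2$plan$array)))
  )
  structure(
    list(stage1 = stage1, confirm1 = confirm1, refinement = ref,
         stage2 = stage2, confirm2 = confirm2,
         best_setting = best_setting, comparison = comparison,
         budget = budget),
    class = "tsto_report"
  )
}

#' Experiment-budget arithmetic: orthogonal array vs full factorial
#'
#' A full-factorial (grid) search over the factors needs
#' `prod(level counts) * replicates` model evaluations; the orthogonal
#' array needs `runs * replicates`. The reduction factor is their ratio
#' (e.g. six 3-level factors with 3 replicates: 2187 vs 54 on L18,
#' a factor of 40.5).
#'
#' @param factors List of [factor_spec()] objects.
#' @param replicates Replicates per run.
#' @param array A `tsto_oa` or array identifier.
#' @return List with `full_factorial`, `array_experiments`, `reduction`.
#' @examples
#' ex <- cvd_example_stage1()
#' experiment_budget(ex$factors, 3, "L18")
#' @export
experiment_budget <- function(factors, replicates, array) {
  factors <- .check_factor_list(factors)
  if (is.character(array)) array <- oa_get(array)
  full <- prod(vapply(factors, function(f) length(f$levels), numeric(1))) *
    replicates
  arr <- array$runs * replicates
  list(full_factorial = full, array_experiments = arr, reduction = full / arr)
}

#' @export
print.tsto_stage <- function(x, ...) {
  cat(sprintf("Taguchi stage on %s: %d runs x %d replicates\n",
              x$plan$array$id, x$plan$array$runs, x$config$replicates))
  cat(sprintf("  grand mean %.4f, grand SN %.3f dB\n",
              attr(x$summary, "grand_mean"), attr(x$summary, "grand_sn")))
  cat("  best levels:",
      paste(names(x$best), vapply(x$best, as.character, ""), sep = "=",
            collapse = ", "), "\n")
  cat("  significant (mean):",
      paste(x$significant_mean, collapse = ", "), "\n")
  cat(sprintf("  predicted mean %.4f (CI %.4f), predicted SN %.3f (CI %.4f)\n",
              x$pred_mean$predicted, x$ci_mean$halfwidth,
              x$pred_sn$predicted, x$ci_sn$halfwidth))
  invisible(x)
}

#' @export
print.tsto_confirmation <- function(x, ...) {
  cat(sprintf("Confirmation (%d runs): mean %.4f, sd %.4f, SN %.3f dB\n",
              length(x$values), x$mean, x$sd, x$sn))
  flag <- function(p) if (is.na(p)) "n/a" else if (p) "PASS" else "FAIL"
  cat("  mean within predicted interval:", flag(x$pass_mean),
      "| SN:", flag(x$pass_sn), "\n")
  invisible(x)
}

#' @export
print.tsto_report <- function(x, ...) {
  cat("Two-stage Taguchi optimization report\n")
  print(x$stage1); print(x$confirm1)
  cat("Refined factors:", paste(names(x$refinement$factors), collapse = ", "),
      "| fixed:", paste(names(x$refinement$fixed), collapse = ", "), "\n")
  print(x$stage2); print(x$confirm2)
  cat("Comparison:\n")
  cmp <- x$comparison
  for (col in c("mean", "sd", "sn")) cmp[[col]] <- round(cmp[[col]], 4)
  print(cmp, row.names = FALSE)
  invisible(x)
}
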