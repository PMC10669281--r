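# Main-effects response tables, pooled ANOVA, additive prediction and
# confirmation confidence intervals.

#' Main-effects response table
#'
#' For each factor, the mean of the per-run response at every level, the
#' effect (max level mean minus min level mean) and the rank (1 = largest
#' effect; ties broken by factor declaration order). The response can be
#' any per-run summary, typically the per-run mean or per-run SN ratio.
#'
#' @param plan A `tsto_plan`.
#' @param response Named numeric vector or data frame (`run`, value) with
#'   one response per run, or a `tsto_summary` together with `kind`.
#' @param kind Label stored on the table (`"mean"` or `"sn"`); when
#'   `response` is a `tsto_summary` it also selects the column.
#' @return A `tsto_response_table`: list with `grand_mean`,
#'   `level_means` (list: factor -> numeric vector over levels),
#'   `effects`, `ranks`, `kind`, `plan`.
#' @examples
#' ex <- cvd_example_stage1()
#' s <- summarize_runs(ex$plan, ex$results)
#' rt <- response_table(ex$plan, s, kind = "mean")
#' rt$effects[["activation"]]  # 0.1619
#' @export
response_table <- function(plan, response, kind = c("mean", "sn")) {
  kind <- match.arg(kind)
  y <- .per_run_response(plan, response, kind)
  grand <- mean(y)
  level_means <- list()
  effects <- numeric(0)
  for (f in plan$factors) {
    idx <- plan_level_index(plan, f$name)
    nlev <- length(f$levels)
    lm <- vapply(seq_len(nlev), function(l) {
      sel <- idx == l
      if (!any(sel)) {
        stop("Factor '", f$name, "' level ", l, " has no runs in the design",
             call. = FALSE)
      }
      mean(y[sel])
    }, numeric(1))
    names(lm) <- as.character(f$levels)
    level_means[[f$name]] <- lm
    effects[f$name] <- max(lm) - min(lm)
  }
  # rank 1 = largest effect; stable tie-break = declaration order
  ord <- order(-effects, seq_along(effects))
  ranks <- integer(length(effects))
  ranks[ord] <- seq_along(effects)
  names(ranks) <- names(effects)
  structure(
    list(grand_mean = grand, level_means = level_means, effects = effects,
         ranks = ranks, kind = kind, plan = plan, response = y),
    class = "tsto_response_table"
  )
}

.per_run_response <- function(plan, response, kind = "mean") {
  runs <- plan$design$run
  if (inherits(response, "tsto_summary")) {
    y <- response[[kind]]
    names(y) <- response$run
  } else if (is.data.frame(response)) {
    stopifnot("run" %in% names(response), ncol(response) >= 2L)
    val_col <- setdiff(names(response), "run")[1L]
    y <- response[[val_col]]
    names(y) <- response$run
  } else {
    y <- response
    if (is.null(names(y))) names(y) <- runs
  }
  y <- y[as.character(runs)]
  if (anyNA(y)) stop("Need exactly one response value per run", call. = FALSE)
  unname(y)
}

#' Main-effects ANOVA with pooling of minor factors into the error term
#'
#' Operates on per-run summary responses (per-run mean or per-run SN), so a
#' design of `a` runs carries `a - 1` total degrees of freedom. The sum of
#' squares of factor f with L levels is
#' `SS_f = (a/L) * sum((levelMean - grandMean)^2)`, each with `L - 1` DF.
#' The error term absorbs the pooled factors' SS and the residual from
#' unassigned array columns: `SSE = SST - sum(unpooled SS)` with
#' `DF_e = (a-1) - sum(unpooled DF)`. Pooled rows carry no F or p;
#' for unpooled rows `F = MS_f / MS_e` with upper-tail p-values.
#' `R^2 = sum(unpooled SS)/SST` and
#' `R^2_adj = 1 - (SSE/DF_e)/(SST/(a-1))`.
#'
#' @inheritParams response_table
#' @param pooled Character vector of factor names pooled into the error
#'   term (may be empty; must leave at least one unpooled factor and at
#'   least 1 error DF).
#' @return A `tsto_anova`: data frame `source`, `df`, `ss`, `ms`, `f`,
#'   `p`, `pooled`, plus error/total rows, with attributes `ve` (error
#'   variance), `error_df`, `r_squared`, `r_squared_adj`, `factor_df`
#'   (named DF of each unpooled factor).
#' @examples
#' ex <- cvd_example_stage1()
#' s <- summarize_runs(ex$plan, ex$results)
#' a <- taguchi_anova(ex$plan, s, pooled = c("hidden_layers", "learning_rate",
#'                                           "moment_rate", "hidden_nodes"))
#' attr(a, "ve")  # 0.003901
#' @export
taguchi_anova <- function(plan, response, pooled = character(),
                          kind = c("mean", "sn")) {
  kind <- match.arg(kind)
  y <- .per_run_response(plan, response, kind)
  nm <- names(plan$factors)
  if (!all(pooled %in% nm)) {
    stop("Pooled set contains unknown factor(s): ",
         paste(setdiff(pooled, nm), collapse = ", "), call. = FALSE)
  }
  unpooled <- setdiff(nm, pooled)
  if (!length(unpooled)) stop("At least one factor must stay unpooled", call. = FALSE)

  a <- length(y)
  grand <- mean(y)
  sst <- sum((y - grand)^2)
  if (sst == 0) stop("All responses are equal; ANOVA is degenerate", call. = FALSE)

  ss <- df <- numeric(length(nm))
  names(ss) <- names(df) <- nm
  for (f in plan$factors) {
    idx <- plan_level_index(plan, f$name)
    nlev <- length(f$levels)
    lm <- vapply(seq_len(nlev), function(l) mean(y[idx == l]), numeric(1))
    ss[f$name] <- (a / nlev) * sum((lm - grand)^2)
    df[f$name] <- nlev - 1L
  }
  err_df <- (a - 1L) - sum(df[unpooled])
  if (err_df < 1L) {
    stop("Pooling leaves no error degrees of freedom (", err_df, ")",
         call. = FALSE)
  }
  sse <- sst - sum(ss[unpooled])
  ve <- sse / err_df

  fval <- pval <- rep(NA_real_, length(nm))
  names(fval) <- names(pval) <- nm
  for (f in unpooled) {
    fval[f] <- (ss[f] / df[f]) / ve
    pval[f] <- f_pvalue(fval[f], df[f], err_df)
  }

  tab <- data.frame(
    source = c(nm, "Error", "Total"),
    df = c(df, err_df, a - 1L),
    ss = c(ss, sse, sst),
    ms = c(ifelse(nm %in% unpooled, ss / df, NA_real_), ve, NA_real_),
    f = c(fval, NA_real_, NA_real_),
    p = c(pval, NA_real_, NA_real_),
    pooled = c(nm %in% pooled, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  structure(tab,
            class = c("tsto_anova", "data.frame"),
            ve = ve, error_df = err_df, sst = sst,
            r_squared = sum(ss[unpooled]) / sst,
            r_squared_adj = 1 - (sse / err_df) / (sst / (a - 1L)),
            factor_df = df[unpooled],
            kind = kind)
}

#' Upper-tail F quantile and p-value
#'
#' Thin wrappers around the F distribution used for ANOVA significance and
#' confirmation confidence intervals: `f_quantile(alpha, df1, df2)` is the
#' value exceeded with probability `alpha`; `f_pvalue(f, df1, df2)` is the
#' upper-tail probability of an observed F statistic.
#'
#' @param alpha Upper-tail probability in (0, 1).
#' @param f Observed F statistic.
#' @param df1,df2 Degrees of freedom (>= 1).
#' @return A quantile or probability.
#' @examples
#' f_quantile(0.05, 1, 13)  # 4.6672
#' @export
f_quantile <- function(alpha, df1, df2) {
  stopifnot(alpha > 0, alpha < 1, df1 >= 1, df2 >= 1)
  stats::qf(alpha, df1, df2, lower.tail = FALSE)
}

#' @rdname f_quantile
#' @export
f_pvalue <- function(f, df1, df2) {
  stopifnot(df1 >= 1, df2 >= 1)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' Factors significant at level alpha in a pooled ANOVA
#'
#' @param anova A `tsto_anova`.
#' @param alpha Screening significance level (default 0.1). A factor is
#'   significant when its unrounded p-value is below `alpha`.
#' @return Character vector of significant factor names.
#' @export
significant_factors <- function(anova, alpha = 0.1) {
  stopifnot(inherits(anova, "tsto_anova"))
  rows <- !is.na(anova$p) & anova$p < alpha
  anova$source[rows]
}

#' Additive main-effects prediction at a chosen setting
#'
#' Predicted response = grand mean + sum over the selected factors of
#' (level mean - grand mean). Only the factors named in `setting`
#' contribute; with an empty setting the prediction is the grand mean.
#' The additivity assumption ignores interactions.
#'
#' @param rt A `tsto_response_table`.
#' @param setting Named list/vector: factor name -> chosen level value.
#' @return A `tsto_prediction`: list with `predicted`, `grand_mean`,
#'   `contributions` (named level-mean deviations) and `setting`.
#' @examples
#' ex <- cvd_example_stage1()
#' rt <- response_table(ex$plan, summarize_runs(ex$plan, ex$results), "mean")
#' predict_additive(rt, list(activation = "tanh", optimizer = "sgd"))$predicted
#' @export
predict_additive <- function(rt, setting = list()) {
  stopifnot(inherits(rt, "tsto_response_table"))
  contrib <- numeric(0)
  for (f in names(setting)) {
    lm <- rt$level_means[[f]]
    if (is.null(lm)) stop("Unknown factor '", f, "'", call. = FALSE)
    key <- as.character(setting[[f]])
    if (!key %in% names(lm)) {
      stop("Factor '", f, "' has no level '", key, "'", call. = FALSE)
    }
    contrib[f] <- lm[[key]] - rt$grand_mean
  }
  structure(
    list(predicted = rt$grand_mean + sum(contrib),
         grand_mean = rt$grand_mean,
         contributions = contrib,
         setting = setting,
         kind = rt$kind),
    class = "tsto_prediction"
  )
}

#' Confirmation confidence interval for an additive prediction
#'
#' Half-width of the confidence interval against which the mean of `r`
#' confirmation runs is compared:
#' `CI = sqrt(F(alpha; 1, df_e) * Ve * (1/n_eff + 1/r))`, where `Ve` is the
#' pooled error variance with `df_e` degrees of freedom and the effective
#' sample size is `n_eff = total runs / (1 + sum of DF of the factors used
#' in the prediction)`.
#'
#' @param anova A `tsto_anova` (supplies `Ve` and `df_e`).
#' @param total_runs Number of runs in the design (e.g. 18 for L18).
#' @param prediction_factors Names of the factors used in the additive
#'   prediction (their DF enter `n_eff`).
#' @param r Number of confirmation runs (>= 1).
#' @param alpha Significance level of the interval (default 0.05).
#' @param center Optional predicted value; when given, the interval
#'   `[center - CI, center + CI]` is included in the result.
#' @return A `tsto_ci`: list with `halfwidth`, `n_eff`, `ve`, `error_df`,
#'   `f_crit`, `alpha`, `r` and (optionally) `center`, `lower`, `upper`.
#' @examples
#' ex <- cvd_example_stage1()
#' s <- summarize_runs(ex$plan, ex$results)
#' a <- taguchi_anova(ex$plan, s, pooled = c("hidden_layers", "learning_rate",
#'                                           "moment_rate", "hidden_nodes"))
#' confidence_halfwidth(a, 18, c("activation", "optimizer"), r = 5)$halfwidth
#' @export
confidence_halfwidth <- function(anova, total_runs, prediction_factors,
                                 r, alpha = 0.05, center = NULL) {
  stopifnot(inherits(anova, "tsto_anova"), r >= 1, total_runs >= 1)
  ve <- attr(anova, "ve")
  df_e <- attr(anova, "error_df")
  if (ve < 0) stop("Pooled error variance is negative", call. = FALSE)
  fdf <- attr(anova, "factor_df")
  unknown <- setdiff(prediction_factors, names(fdf))
  if (length(unknown)) {
    stop("Prediction factor(s) not in the unpooled ANOVA rows: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n_eff <- total_runs / (1 + sum(fdf[prediction_factors]))
  f_crit <- f_quantile(alpha, 1, df_e)
  ci <- sqrt(f_crit * ve * (1 / n_eff + 1 / r))
  out <- list(halfwidth = ci, n_eff = n_eff, ve = ve, error_df = df_e,
              f_crit = f_crit, alpha = alpha, r = r)
  if (!is.null(center)) {
    out$center <- center
    out$lower <- center - ci
    out$upper <- center + ci
  }
  structure(out, class = "tsto_ci")
}

#' Best level of each factor from the mean and SN response tables
#'
#' Picks, per factor, the level maximizing the mean-response level mean;
#' an exact tie is broken by the higher SN level mean, then by the lower
#' level index (smaller resource).
#'
#' @param rt_mean Response table of per-run means.
#' @param rt_sn Response table of per-run SN ratios (same plan).
#' @return Named list: factor name -> best level value.
#' @export
select_best_levels <- function(rt_mean, rt_sn) {
  stopifnot(inherits(rt_mean, "tsto_response_table"),
            inherits(rt_sn, "tsto_response_table"))
  best <- list()
  for (f in names(rt_mean$level_means)) {
    lm <- rt_mean$level_means[[f]]
    ls <- rt_sn$level_means[[f]]
    cand <- which(lm == max(lm))
    if (length(cand) > 1L) cand <- cand[ls[cand] == max(ls[cand])]
    pick <- cand[1L]  # lowest level index among remaining ties
    fac <- rt_mean$plan$factors[[f]]
    best[[f]] <- fac$levels[pick]
  }
  best
}

#' @export
print.tsto_response_table <- function(x, ...) {
  cat(sprintf("Response table (%s); grand mean %.4f\n", x$kind, x$grand_mean))
  nlev <- max(vapply(x$level_means, length, 0L))
  mat <- sapply(x$level_means, function(lm) c(lm, rep(NA, nlev - length(lm))))
  rownames(mat) <- paste("Level", seq_len(nlev))
  mat <- rbind(mat, Effect = x$effects, Rank = x$ranks)
  print(round(mat, 4))
  invisible(x)
}

#' @export
print.tsto_anova <- function(x, ...) {
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 6)
  df$ms <- signif(df$ms, 4)
  df$f <- round(df$f, 2)
  df$p <- round(df$p, 3)
  df$source <- ifelse(df$pooled, paste0(df$source, " *"), df$source)
  df$pooled <- NULL
  print(df, row.names = FALSE, na.print = "")
  cat(sprintf("R-sq %.2f%%  R-sq(adj) %.2f%%   (* pooled into error)\n",
              100 * attr(x, "r_squared"), 100 * attr(x, "r_squared_adj")))
  invisible(x)
}

#' @export
print.tsto_prediction <- function(x, ...) {
  cat(sprintf("Additive prediction (%s): %.4f  (grand mean %.4f, %d factor(s))\n",
              x$kind, x$predicted, x$grand_mean, length(x$contributions)))
  invisible(x)
}

#' @export
print.tsto_ci <- function(x, ...) {
  cat(sprintf(
    "CI half-width %.4f (alpha %.2f, F %.4f, Ve %.3g, df_e %d, n_eff %.3g, r %d)\n",
    x$halfwidth, x$alpha, x$f_crit, x$ve, x$error_df, x$n_eff, x$r))
  if (!is.null(x$center)) {
    cat(sprintf("  interval: %.4f  (%.4f, %.4f)\n", x$center, x$lower, x$upper))
  }
  invisible(x)
}
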