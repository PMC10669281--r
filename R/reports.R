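# Report writing: per-stage CSV bundles at full precision plus
# display-rounded variants mirroring the conventional table layout
# (4 decimals on the accuracy scale, 3 on SN, 3 on p-values).

.rt_as_df <- function(rt) {
  nlev <- max(vapply(rt$level_means, length, 0L))
  df <- data.frame(row = c(paste0("level_", seq_len(nlev)), "effect", "rank"))
  for (f in names(rt$level_means)) {
    lm <- rt$level_means[[f]]
    df[[f]] <- c(lm, rep(NA, nlev - length(lm)), rt$effects[[f]], rt$ranks[[f]])
  }
  df
}

.round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  df
}

#' Write the CSV bundle of one analyzed stage
#'
#' Writes deterministic files into `dir`: `summary.csv` (per-run design,
#' mean, SD, SN), `response_mean.csv` / `response_sn.csv` (level means,
#' effect, rank), `anova_mean.csv` / `anova_sn.csv` (source, DF, SS, MS,
#' F, p, pooled flag), `prediction.csv` (predictions with confidence
#' half-widths and intervals) and `eval_log.csv`. Full-precision values;
#' a `*_display.csv` twin of each table is rounded the way such tables
#' are conventionally printed.
#'
#' @param stage A `tsto_stage`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
write_stage_reports <- function(stage, dir) {
  stopifnot(inherits(stage, "tsto_stage"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name, display_digits = NULL) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    files <<- c(files, path)
    if (!is.null(display_digits)) {
      dpath <- file.path(dir, paste0(name, "_display.csv"))
      utils::write.csv(.round_df(df, display_digits), dpath,
                       row.names = FALSE, quote = FALSE, na = "")
      files <<- c(files, dpath)
    }
  }
  sm <- as.data.frame(stage$summary)
  sm$sn <- round(sm$sn, 10)  # strip FP dust for byte-stable output
  emit(sm, "summary", display_digits = 4)
  emit(.rt_as_df(stage$rt_mean), "response_mean", display_digits = 4)
  emit(.rt_as_df(stage$rt_sn), "response_sn", display_digits = 4)
  emit(as.data.frame(stage$anova_mean), "anova_mean", display_digits = 6)
  emit(as.data.frame(stage$anova_sn), "anova_sn", display_digits = 6)
  pred <- data.frame(
    response = c("mean", "sn"),
    predicted = c(stage$pred_mean$predicted, stage$pred_sn$predicted),
    ci_halfwidth = c(stage$ci_mean$halfwidth, stage$ci_sn$halfwidth),
    lower = c(stage$ci_mean$lower, stage$ci_sn$lower),
    upper = c(stage$ci_mean$upper, stage$ci_sn$upper),
    n_eff = c(stage$ci_mean$n_eff, stage$ci_sn$n_eff),
    ve = c(stage$ci_mean$ve, stage$ci_sn$ve),
    error_df = c(stage$ci_mean$error_df, stage$ci_sn$error_df),
    factors = rep(paste(stage$retained_mean, collapse = "+"), 2)
  )
  emit(pred, "prediction", display_digits = 4)
  emit(stage$eval_log, "eval_log")
  invisible(files)
}

#' Write the full two-stage report bundle
#'
#' Stage bundles under `stage1/` and `stage2/` (see
#' [write_stage_reports()]), a `comparison.csv` in the stage-comparison
#' shape (settings, confirmation mean, SD, SN, improvement row), a
#' `confirmations.csv`, a plain-text narrative `report.txt`, and a
#' JSON-lines `manifest.jsonl` with one record per logged evaluation.
#'
#' @param report A `tsto_report` from [run_tsto()].
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "tsto_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(write_stage_reports(report$stage1, file.path(dir, "stage1")),
             write_stage_reports(report$stage2, file.path(dir, "stage2")))

  cmp_path <- file.path(dir, "comparison.csv")
  utils::write.csv(report$comparison, cmp_path, row.names = FALSE,
                   quote = FALSE, na = "")
  conf <- rbind(
    data.frame(stage = "stage1", rep = seq_along(report$confirm1$values),
               response = report$confirm1$values),
    data.frame(stage = "stage2", rep = seq_along(report$confirm2$values),
               response = report$confirm2$values)
  )
  conf_path <- file.path(dir, "confirmations.csv")
  utils::write.csv(conf, conf_path, row.names = FALSE, quote = FALSE)

  txt_path <- file.path(dir, "report.txt")
  con <- file(txt_path, open = "wt")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  print(report)
  sink(); close(con); on.exit()

  manifest_path <- file.path(dir, "manifest.jsonl")
  log <- rbind(cbind(stage = "stage1", report$stage1$eval_log),
               cbind(stage = "stage2", report$stage2$eval_log))
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE)
  }, "")
  writeLines(lines, manifest_path)

  invisible(c(files, cmp_path, conf_path, txt_path, manifest_path))
}
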