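#' Write a cohort report to disk
#'
#' Emits flat CSV tables for every populated analysis, a JSON summary of the
#' test results, a JSON-lines exclusion log (machine-checkable accounting of
#' retained/excluded subjects per analysis), a config echo, and a manifest
#' listing every written file with its MD5 checksum.
#'
#' @param report A `gng_report` from [run_analyses()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest tibble.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "gng_report"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create `%s`.", outdir), class = "gng_io_error")
  }
  written <- character(0)
  put_csv <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(invisible(NULL))
    path <- file.path(outdir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }

  put_csv(report$behavior_table, "behavior_table")
  put_csv(report$behavior_subjects, "behavior_subjects")
  put_csv(report$a4_wilcoxon, "a4_wilcoxon")
  put_csv(report$a4_tertile_pea, "a4_tertile_pea")
  put_csv(report$a3_areas, "a3_areas")
  put_csv(report$a3_anova, "a3_anova")
  put_csv(report$a3_posthoc, "a3_posthoc")
  for (nm in c("a1_erp", "a1_ersp", "a2_erp", "a2_ersp")) {
    pt <- report[[nm]]
    if (!is.null(pt)) {
      put_csv(tidy(pt), nm)
      put_csv(dplyr::mutate(pt$runs, test = nm, .before = 1), paste0(nm, "_runs"))
    }
  }
  for (nm in c("a4_tertile_tests", "a5_rsi_behavior_tests", "a5_rsi_neural_tests")) {
    tt <- report[[nm]]
    if (!is.null(tt)) {
      put_csv(tt$friedman, paste0(nm, "_friedman"))
      put_csv(tt$posthoc, paste0(nm, "_posthoc"))
    }
  }
  put_csv(report$a5_rsi_behavior, "a5_rsi_behavior")
  put_csv(report$a5_rsi_neural, "a5_rsi_neural")

  # structured exclusion log, one JSON object per subject x analysis
  log_path <- file.path(outdir, "exclusions.jsonl")
  con <- file(log_path, "w")
  for (analysis in names(report$exclusions)) {
    df <- report$exclusions[[analysis]]
    for (i in seq_len(nrow(df))) {
      rec <- c(list(analysis = analysis), as.list(df[i, ]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"),
        con)
    }
  }
  close(con)
  written <- c(written, log_path)

  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(unclass(report$config), cfg_path, auto_unbox = TRUE,
    digits = NA)
  written <- c(written, cfg_path)

  summary_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(glance(report), summary_path, auto_unbox = TRUE,
    digits = NA, dataframe = "rows")
  written <- c(written, summary_path)

  manifest <- tibble::tibble(
    file = basename(written),
    md5 = unname(tools::md5sum(written))
  )
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @export
print.gng_report <- function(x, ...) {
  cat("<gng_report> go/no-go error-processing cohort analysis\n")
  cat("  analyses:", paste(x$analyses, collapse = ", "), "\n")
  if (!is.null(x$behavior_table)) {
    cat(sprintf("  behavioral table: %d measures over %d subjects\n",
      nrow(x$behavior_table), max(x$behavior_table$n)))
  }
  for (nm in c("a1_erp", "a1_ersp", "a2_erp", "a2_ersp")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %s: t in [%.2f, %.2f], %d significant run(s)\n", nm,
        x[[nm]]$t_range[1], x[[nm]]$t_range[2], nrow(x[[nm]]$runs)))
    }
  }
  if (!is.null(x$a3_anova)) {
    for (i in seq_len(nrow(x$a3_anova))) {
      cat(sprintf("  a3 %s: F(%d,%d) = %.2f, p = %.3g\n", x$a3_anova$measure[i],
        x$a3_anova$df1[i], x$a3_anova$df2[i], x$a3_anova$F[i], x$a3_anova$p[i]))
    }
  }
  invisible(x)
}
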