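#' Tidy a sample-wise permutation test
#'
#' @param x A `gng_permtest`.
#' @param ... Unused.
#' @return A tibble with one row per time sample: `time_ms`, `t`, `p`,
#'   `significant`.
#' @exportS3Method generics::tidy
tidy.gng_permtest <- function(x, ...) {
  tibble::tibble(time_ms = x$time_ms, t = x$t, p = x$p,
    significant = x$significant)
}

#' One-row summary of a sample-wise permutation test
#'
#' @param x A `gng_permtest`.
#' @param ... Unused.
#' @return A tibble with the t range, number/extent of significant runs and
#'   the test configuration.
#' @exportS3Method generics::glance
glance.gng_permtest <- function(x, ...) {
  tibble::tibble(
    t_min = x$t_range[1], t_max = x$t_range[2],
    n_significant = sum(x$significant), n_runs = nrow(x$runs),
    run_start_ms = if (nrow(x$runs)) min(x$runs$start_ms) else NA_real_,
    run_end_ms = if (nrow(x$runs)) max(x$runs$end_ms) else NA_real_,
    alpha = x$alpha, min_consec = x$min_consec, n_perm = x$n_perm,
    n_subjects = x$n_subjects
  )
}

#' Flat summary of a cohort report
#'
#' @param x A `gng_report`.
#' @param ... Unused.
#' @return A tibble with one row per executed test (permutation contrasts,
#'   rank tests, ANOVAs) and its headline numbers.
#' @exportS3Method generics::glance
glance.gng_report <- function(x, ...) {
  rows <- list()
  add <- function(test, statistic, value, p, n, r = NA_real_, extra = NA_character_) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(test = test,
      statistic = statistic, value = value, p = p, n = n, r = r, note = extra)
  }
  for (nm in c("a1_erp", "a1_ersp", "a2_erp", "a2_ersp")) {
    pt <- x[[nm]]
    if (is.null(pt)) next
    add(nm, "t_min", pt$t_range[1], NA_real_, pt$n_subjects)
    add(nm, "t_max", pt$t_range[2], NA_real_, pt$n_subjects)
    add(nm, "n_runs", nrow(pt$runs), NA_real_, pt$n_subjects,
      extra = if (nrow(pt$runs)) {
        paste(sprintf("[%g,%g]ms", pt$runs$start_ms, pt$runs$end_ms), collapse = ";")
      } else NA_character_)
  }
  if (!is.null(x$a4_wilcoxon)) {
    for (i in seq_len(nrow(x$a4_wilcoxon))) {
      w <- x$a4_wilcoxon[i, ]
      add(paste0("a4_", w$comparison), "Z", w$Z, w$p, w$n, w$r)
    }
  }
  for (nm in c("a4_tertile_tests", "a5_rsi_behavior_tests", "a5_rsi_neural_tests")) {
    tt <- x[[nm]]
    if (is.null(tt)) next
    add(nm, "friedman_chisq", tt$friedman$chisq, tt$friedman$p, tt$friedman$n)
    for (i in seq_len(nrow(tt$posthoc))) {
      ph <- tt$posthoc[i, ]
      add(paste0(nm, "_", ph$comparison), "Z", ph$Z, ph$p, ph$n, ph$r)
    }
  }
  if (!is.null(x$a3_anova)) {
    for (i in seq_len(nrow(x$a3_anova))) {
      a <- x$a3_anova[i, ]
      add(paste0("a3_", a$measure), "F", a$F, a$p, a$df2 + a$df1 + 1)
    }
  }
  if (!is.null(x$a3_posthoc)) {
    for (i in seq_len(nrow(x$a3_posthoc))) {
      ph <- x$a3_posthoc[i, ]
      add(paste0("a3_", ph$measure, "_", ph$comparison), "t", ph$t, ph$p, ph$n, ph$r)
    }
  }
  dplyr::bind_rows(rows)
}

#' @exportS3Method generics::tidy
tidy.gng_roi <- function(x, ...) {
  tibble::tibble(time_ms = x$time_ms, value = x$value,
    condition = attr(x, "condition") %||% NA_character_,
    unit = attr(x, "unit"), n_epochs = attr(x, "n_epochs"))
}
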