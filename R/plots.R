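#' Plot a region-of-interest waveform
#'
#' @param object A `gng_roi` series (uV or dB).
#' @param ... Further `gng_roi` series to overlay (named arguments become
#'   legend labels).
#' @return A ggplot object: value against response-locked time, with the
#'   button press at 0 ms.
#' @exportS3Method ggplot2::autoplot
autoplot.gng_roi <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, inherits, logical(1), what = "gng_roi")]
  all_series <- c(list(object), extra)
  labels <- vapply(seq_along(all_series), function(i) {
    attr(all_series[[i]], "condition") %||% paste0("series", i)
  }, character(1))
  df <- dplyr::bind_rows(lapply(seq_along(all_series), function(i) {
    tibble::tibble(time_ms = all_series[[i]]$time_ms,
      value = all_series[[i]]$value, condition = labels[i])
  }))
  unit <- attr(object, "unit") %||% "uV"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$value,
    colour = .data$condition)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Time from response (ms)",
      y = if (unit == "dB") "Power (dB)" else "Amplitude (uV)",
      colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sample-wise permutation test
#'
#' @param object A `gng_permtest`.
#' @param ... Unused.
#' @return A ggplot of the observed t course with significant runs shaded.
#' @exportS3Method ggplot2::autoplot
autoplot.gng_permtest <- function(object, ...) {
  df <- tidy(object)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$t)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_line(linewidth = 0.7)
  if (nrow(object$runs)) {
    g <- g + ggplot2::geom_rect(
      data = object$runs, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
        ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.15)
  }
  g + ggplot2::labs(x = "Time from response (ms)", y = "Paired t",
    subtitle = sprintf("p < %g in runs of >= %d samples", object$alpha,
      object$min_consec)) +
    ggplot2::theme_minimal()
}

#' Tertile summary bar chart
#'
#' Means with standard-error bars of a per-subject tertile measure (e.g.
#' post-error accuracy or RSI across post-error-slowing tertiles).
#'
#' @param df Tibble with a `subject` column and three tertile columns.
#' @param cols The three column names, tertile 1 to 3.
#' @param ylab Axis label.
#' @return A ggplot object.
#' @export
plot_tertiles <- function(df, cols, ylab = "Value") {
  long <- tidyr::pivot_longer(df[, c("subject", cols)], -"subject",
    names_to = "tertile", values_to = "value")
  long$tertile <- factor(long$tertile, levels = cols, labels = c("1", "2", "3"))
  agg <- dplyr::summarise(dplyr::group_by(long, .data$tertile),
    mean = mean(.data$value), se = sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$tertile, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
      ymax = .data$mean + .data$se), width = 0.15) +
    ggplot2::labs(x = "Post-error slowing tertile", y = ylab) +
    ggplot2::theme_minimal()
}
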