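#' Forest plot of reporting odds ratios with confidence intervals
#'
#' Draws one row per drug — point estimate and Woolf confidence interval on
#' a log-scaled axis with a reference line at ROR = 1 — ordered by
#' ascending ROR from the top.
#'
#' @param results A tibble with `ingredient`, `ror`, `ci_low`, `ci_high`
#'   (e.g. from [flagged_signals()], [ibd_candidates()] or
#'   `tidy(<ror_screen>)`).
#' @param title Plot title.
#' @return A ggplot object.
#' @examples
#' ibd_candidates() |>
#'   restrict_to_classes(ibd_class_map()) |>
#'   plot_forest()
#' @export
plot_forest <- function(results, title = "Reporting odds ratios (95% CI)") {
  if (!is.data.frame(results) ||
      !all(c("ingredient", "ror", "ci_low", "ci_high") %in% names(results))) {
    abort_validation("`results` needs ingredient, ror, ci_low, ci_high columns.")
  }
  df <- as_tibble(results)
  df$ingredient <- stats::reorder(df$ingredient, -df$ror)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$ingredient)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.25
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Reporting odds ratio (log scale)", y = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of a screen's tested family
#'
#' @param object A `ror_screen` object.
#' @param flagged_only Plot only flagged signals (default) or the whole
#'   tested family.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ror_screen
#' @export
autoplot.ror_screen <- function(object, flagged_only = TRUE, ...) {
  res <- object$results
  if (flagged_only) {
    res <- res[res$inverse_flag | res$positive_flag, , drop = FALSE]
  }
  plot_forest(res)
}
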