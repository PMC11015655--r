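# ggplot2 display layer: forest plots for results tables and power curves.

#' Forest plot of a results table
#'
#' Draws point estimates with confidence intervals for a tidy results table
#' (one row per outcome/model), faceted by outcome, with optional dashed
#' smallest-effect-size-of-interest guides, mirroring the panel layout used
#' for observational-vs-MR comparisons.
#'
#' @param results Tibble with `outcome`, `model`, `estimate`, `ci_low`,
#'   `ci_high` columns (e.g. the `results_models.tsv` of a run).
#' @param sesoi Optional positive bound drawn as dashed vertical guides at
#'   `+/- sesoi`.
#' @return A ggplot object.
#' @export
plot_forest <- function(results, sesoi = NULL) {
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = .data$estimate, y = .data$model)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~ outcome, scales = "free_x") +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(sesoi)) {
    p <- p + ggplot2::geom_vline(xintercept = c(-sesoi, sesoi),
                                 linetype = "dashed", colour = "steelblue")
  }
  p
}

#' Forest plot method for MR result tables
#' @param object An `mr_result` tibble.
#' @param ... Passed to [plot_forest()].
#' @importFrom ggplot2 autoplot
#' @export
autoplot.mr_result <- function(object, ...) {
  tab <- tidy(object)
  tab$model <- tab$method
  tab$outcome <- ifelse(is.na(tab$outcome), "outcome", tab$outcome)
  plot_forest(tab, ...)
}

#' Plot a grid of power curves
#'
#' @param power_tab Long power table from [power_grid()].
#' @return A ggplot of power against effect size, coloured by sample size,
#'   faceted by family (and prevalence where present).
#' @export
plot_power <- function(power_tab) {
  ggplot2::ggplot(power_tab,
                  ggplot2::aes(x = .data$d, y = .data$power,
                               colour = factor(.data$n))) +
    ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ family) +
    ggplot2::labs(x = "Cohen's D", y = "power", colour = "N") +
    ggplot2::theme_minimal()
}
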