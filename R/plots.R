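#' Plot a Monte Carlo summary surface
#'
#' Grouped bar chart of one aggregate per scenario, coloured by design and
#' faceted by treatment-bias variant — the standard way the four result
#' surfaces (change, absolute error, percent of true change, percent
#' standard error) are displayed.
#'
#' @param object An `mc_summary` tibble from [summarize_experiment()].
#' @param metric Column to display: `"mean_change"`, `"mean_diff"`,
#'   `"mean_abs_diff"`, `"pct_of_true"` or `"pct_se"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mc_summary
#' @export
autoplot.mc_summary <- function(object, metric = c("mean_change", "mean_diff",
                                                   "mean_abs_diff",
                                                   "pct_of_true", "pct_se"),
                                ...) {
  metric <- match.arg(metric)
  lab <- c(mean_change = "Mean estimated change (t/ha)",
           mean_diff = "Mean deviation from true change (t/ha)",
           mean_abs_diff = "Mean |deviation| from true change (t/ha)",
           pct_of_true = "Estimate in percent of true change (%)",
           pct_se = "Percent standard error (%)")[[metric]]
  df <- dplyr::mutate(object, bias_label = ifelse(.data$bias,
                                                  "with treatment bias",
                                                  "no treatment bias"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data[[metric]],
                                   fill = .data$design)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~bias_label) +
    ggplot2::labs(x = NULL, y = lab, fill = "design") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname autoplot.mc_summary
#' @export
plot_mc_summary <- function(object, metric = "mean_change", ...) {
  autoplot.mc_summary(object, metric = metric, ...)
}

#' Scatter plot of a two-occasion plot panel
#'
#' Occasion-2 (disturbed) against occasion-1 biomass, affected plots
#' highlighted; the 1:1 line separates plots that gained from plots that
#' lost biomass.
#'
#' @param panel A plot panel tibble from [apply_scenario()].
#' @return A ggplot object.
#' @export
plot_panel <- function(panel) {
  ggplot2::ggplot(panel, ggplot2::aes(x = .data$x_t1, y = .data$y_t2_disturbed,
                                      colour = .data$affected)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Occasion-1 AGB (t/ha)", y = "Occasion-2 AGB (t/ha)",
                  colour = "affected") +
    ggplot2::theme_minimal()
}
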