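#' Trajectories of community metrics over years
#'
#' Mean and standard error of one or more metric columns per assemblage and
#' year, drawn as lines with error bars and facetted by metric.
#'
#' @param metrics per plot-year tibble from [community_metrics()].
#' @param vars metric columns to draw.
#' @param colour column mapped to colour (default `assemblage`).
#' @return a ggplot.
#' @export
plot_metric_trajectories <- function(metrics,
                                     vars = c("fdis", "richness", "evenness"),
                                     colour = "assemblage") {
  long <- metrics |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "metric") |>
    dplyr::group_by(.data$metric, .data$year,
                    group = .data[[colour]]) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$mean,
                                     colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             size = 0.2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "years since sowing", y = NULL, colour = colour) +
    ggplot2::theme_minimal()
}

#' Stacked cover shares of regeneration strategies over years
#'
#' @param props tibble from [strategy_proportions()].
#' @return a ggplot (stacked area chart of cover shares).
#' @export
plot_strategy_proportions <- function(props) {
  props$strategy <- factor(props$strategy, levels = regen_levels())
  ggplot2::ggplot(props, ggplot2::aes(.data$year, .data$cover_share,
                                      fill = .data$strategy)) +
    ggplot2::geom_area() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "years since sowing", y = "share of total cover",
                  fill = "regeneration strategy") +
    ggplot2::theme_minimal()
}

#' SES trajectories per assemblage
#'
#' @param ses tibble from [ses_table()] (optionally with design factors).
#' @return a ggplot of standardized effect sizes over years, zero line
#'   marked.
#' @export
plot_ses <- function(ses) {
  ggplot2::ggplot(dplyr::filter(ses, .data$ses_defined),
                  ggplot2::aes(.data$year, .data$ses,
                               colour = .data$assemblage)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::labs(x = "years since sowing",
                  y = "SES of functional dispersion") +
    ggplot2::theme_minimal()
}
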