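# report colors -> plot fills; bright/deep red kept visually distinct
RISK_FILLS <- c(
  green = "#4daf4a", yellow = "#ffd92f",
  bright_red = "#e41a1c", deep_red = "#67000d"
)

#' Plot the risk matrix of a profile
#'
#' Tile plot of likelihood x severity with each cell labelled by its risk
#' factor and filled by its category color.
#'
#' @param profile a risk profile; see [default_risk_profile()].
#' @return a ggplot object.
#' @export
plot_risk_matrix <- function(profile = default_risk_profile()) {
  grid <- tidyr::expand_grid(
    likelihood = profile$likelihood$score,
    severity = profile$severity$score
  )
  cells <- compute_risk_factor(grid$likelihood, grid$severity, profile)
  ggplot2::ggplot(
    cells,
    ggplot2::aes(
      x = factor(.data$severity), y = factor(.data$likelihood),
      fill = .data$color, label = .data$risk_factor
    )
  ) +
    ggplot2::geom_tile(color = "grey20") +
    ggplot2::geom_text(size = 6) +
    ggplot2::scale_fill_manual(values = RISK_FILLS, guide = "none") +
    ggplot2::labs(
      x = "Severity score (NO2 concentration band)",
      y = "Likelihood score (shift occupancy band)",
      title = "Risk matrix: risk factor = likelihood x severity"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the risk-category distribution of a scored campaign
#'
#' Stacked bar chart of the share of locations in each risk category, per
#' hospital and season.
#'
#' @param object a scored table from [run_assessment()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.no2_risk_table <- function(object, ...) {
  dist <- risk_distribution(object)
  key <- unique(object[, c("category", "color")])
  fills <- stats::setNames(RISK_FILLS[key$color], key$category)
  ggplot2::ggplot(
    dist,
    ggplot2::aes(x = .data$season, y = .data$percent, fill = .data$category)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~hospital_id, nrow = 1) +
    ggplot2::scale_fill_manual(values = fills) +
    ggplot2::labs(
      x = NULL, y = "% of locations",
      title = "Risk-category distribution by hospital and season"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
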