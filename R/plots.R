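# ggplot2 displays for the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_hline geom_vline geom_segment geom_text labs theme_minimal
#'   coord_equal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a linear genetic trend
#'
#' Scatter of breeding values against the regressor year with the fitted
#' OLS line (and optionally a loess curve).
#'
#' @param object A `trend_fit`.
#' @param loess_curve Optional tibble from [fit_loess_trend()].
#' @param ... Unused.
#' @exportS3Method
autoplot.trend_fit <- function(object, loess_curve = NULL, ...) {
  df <- object$data
  p <- ggplot(df, aes(x = .data$year, y = .data$value)) +
    geom_point(alpha = 0.5, colour = "grey40") +
    geom_line(data = tibble(
      year = range(df$year),
      value = object$intercept + object$slope * range(df$year)
    ), colour = "#B2182B", linewidth = 0.9) +
    labs(x = object$regressor, y = "breeding value (kg/ha)",
         subtitle = sprintf("%.2f kg/ha/year (%.3f%% per annum)",
                            object$slope, object$percent_per_annum)) +
    theme_minimal()
  if (!is.null(loess_curve)) {
    p <- p + geom_line(data = rename(loess_curve, value = "fitted"),
                       colour = "#2166AC", linetype = 2)
  }
  p
}

#' Plot per-season Cullis heritabilities
#'
#' @param object A `stage1_result`.
#' @param ... Unused.
#' @exportS3Method
autoplot.stage1_result <- function(object, ...) {
  ggplot(object$h2, aes(x = factor(.data$year), y = .data$h2)) +
    geom_col(fill = "#2166AC") +
    facet_wrap(~season) +
    labs(x = "year", y = expression(H^2)) +
    theme_minimal()
}

#' GGE biplot
#'
#' Genotype scores (row metric preserving) and environment vectors on the
#' first two principal axes, with the average-environment axis and the
#' ideal point used for stability ranking.
#'
#' @param object A `gge_result`.
#' @param ... Unused.
#' @exportS3Method
autoplot.gge_result <- function(object, ...) {
  g <- as_tibble(object$genotype_scores, rownames = "genotype")
  e <- as_tibble(object$environment_scores, rownames = "environment")
  sc <- max(abs(g$PC1), abs(g$PC2)) / max(abs(e$PC1), abs(e$PC2))
  e <- mutate(e, PC1 = .data$PC1 * sc, PC2 = .data$PC2 * sc)
  axis <- object$mean_env_axis * max(abs(g$PC1))
  ggplot(g, aes(x = .data$PC1, y = .data$PC2)) +
    geom_hline(yintercept = 0, colour = "grey80") +
    geom_vline(xintercept = 0, colour = "grey80") +
    geom_segment(data = e, aes(xend = 0, yend = 0), colour = "#2166AC") +
    geom_text(data = e, aes(label = .data$environment),
              colour = "#2166AC", vjust = -0.5, size = 3) +
    geom_segment(x = -axis[1], y = -axis[2], xend = axis[1], yend = axis[2],
                 linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.7) +
    geom_text(aes(label = .data$genotype), vjust = -0.6, size = 2.8) +
    geom_point(data = tibble(PC1 = object$ideal_point[1],
                             PC2 = object$ideal_point[2]),
               shape = 8, size = 3, colour = "#B2182B") +
    labs(x = sprintf("PC1 (%.1f%%)", object$pc_variance_pct[1]),
         y = sprintf("PC2 (%.1f%%)", object$pc_variance_pct[2])) +
    coord_equal() +
    theme_minimal()
}

#' Diversity biplot of an A-matrix PCA
#'
#' @param pca Result of [pca_on_a()].
#' @param highlight Optional genotype ids to emphasize (e.g. an elite
#'   panel).
#' @export
plot_a_biplot <- function(pca, highlight = NULL) {
  df <- mutate(pca$scores,
               highlighted = .data$genotype %in% (highlight %||% character()))
  ggplot(df, aes(x = .data$PC1, y = .data$PC2,
                 colour = .data$highlighted)) +
    geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#B2182B"),
                                 guide = "none") +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * pca$explained[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * pca$explained[2])) +
    theme_minimal()
}
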