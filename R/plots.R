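#' Plot a node-age comparison
#'
#' Scatter of estimate against reference node ages with the through-origin
#' regression line (dashed) and the 1:1 line (dotted). Calibrated nodes are
#' drawn as triangles, uncalibrated ones as circles; reference intervals,
#' when present, appear as horizontal error bars.
#'
#' @param object A `chrono_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chrono_comparison <- function(object, ...) {
  nodes <- object$nodes
  beta <- object$metrics$beta
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$t_ref, y = .data$t_est))
  if (any(!is.na(nodes$ref_lo))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ref_lo, xmax = .data$ref_hi),
      height = 0, linewidth = 0.3, colour = "grey60", na.rm = TRUE)
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey40") +
    ggplot2::geom_abline(slope = beta, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$calibrated), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                name = "calibrated") +
    ggplot2::labs(
      x = sprintf("reference node age (%s)",
                  object$method_ref %||% "reference"),
      y = sprintf("estimated node age (%s)",
                  object$method_est %||% "estimate"),
      subtitle = sprintf("beta = %.3f, R² = %.3f, D̄ = %.1f%%",
                         beta, object$metrics$r2, object$metrics$d_bar)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Distribution of a per-dataset statistic across methods
#'
#' Box-and-jitter plot of one comparison statistic (slope, mean normalized
#' difference, coverage, or median uncertainty width) across datasets,
#' grouped by estimating method.
#'
#' @param results A tibble of per-dataset [glance()] rows.
#' @param statistic Column to plot (default `"beta"`).
#' @return A ggplot object.
#' @export
plot_metric_distribution <- function(results, statistic = "beta") {
  stopifnot(statistic %in% names(results))
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$method_est, y = .data[[statistic]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1.5) +
    ggplot2::labs(x = NULL, y = statistic) +
    ggplot2::theme_minimal()
}
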