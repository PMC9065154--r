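# ggplot2 visualizations for each result type.

#' @export
autoplot.shape_space <- function(object, ...) {
  df <- object$scores
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey70")
  if ("clade_group" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$clade_group),
                                 size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$percent_variance[1]),
      y = sprintf("PC2 (%.1f%%)", object$percent_variance[2]),
      colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sma_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = object$x_name, y = object$y_name,
                  subtitle = sprintf("SMA slope %.3g, r = %.3f",
                                     object$slope, object$r)) +
    ggplot2::theme_minimal()
}

#' Boxplots of the biomechanical scores by group
#'
#' One panel each for mechanical advantage, flexor-tubercle development,
#' and hypothesized output, grouped by `clade_group`.
#'
#' @param scores A [claw_scores()] tibble.
#' @return A ggplot object.
#' @export
plot_mechanics <- function(scores) {
  long <- scores |>
    tidyr::pivot_longer(c("MA", "DFT", "output"),
                        names_to = "metric", values_to = "value") |>
    mutate(metric = factor(.data$metric, levels = c("MA", "DFT", "output")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$clade_group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' @export
autoplot.tps_warp <- function(object, ...) {
  g <- object$grid
  ggplot2::ggplot() +
    ggplot2::geom_path(data = g,
                       ggplot2::aes(x = .data$x_warped, y = .data$y_warped,
                                    group = .data$row),
                       colour = "grey65", linewidth = 0.3) +
    ggplot2::geom_path(data = g,
                       ggplot2::aes(x = .data$x_warped, y = .data$y_warped,
                                    group = .data$col),
                       colour = "grey65", linewidth = 0.3) +
    ggplot2::geom_point(data = object$consensus,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "grey50", size = 2) +
    ggplot2::geom_point(data = object$target,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "black", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
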