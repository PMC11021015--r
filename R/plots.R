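# Optional plots (ggplot2 is a suggested, not required, dependency).

#' Histogram of scores with the fitted mixture overlaid
#'
#' @param scores Numeric vector of scores used in the fit.
#' @param mixture A `gaussian_mixture3` from [fit_mixture()].
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_score_mixture <- function(scores, mixture, bins = 80L) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_score_mixture() needs the ggplot2 package")
  }
  grid <- seq(min(scores), max(scores), length.out = 512L)
  dens <- tibble::tibble(score = grid, density = dmixture3(grid, mixture))
  ggplot2::ggplot(tibble::tibble(score = scores), ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey80", color = "grey50"
    ) +
    ggplot2::geom_line(
      data = dens, ggplot2::aes(y = .data$density),
      color = "steelblue", linewidth = 0.8
    ) +
    ggplot2::geom_vline(
      xintercept = mixture$threshold,
      linetype = "dashed", color = "firebrick"
    ) +
    ggplot2::labs(
      x = "abundance score", y = "density",
      title = sprintf("Low-abundance threshold t* = %.3f", mixture$threshold)
    ) +
    ggplot2::theme_minimal()
}

#' Abundance-activity quadrant plot
#'
#' 2D histogram of abundance vs activity scores with the two thresholds.
#'
#' @param merged Output of [classify_quadrants()].
#' @param t_abund,t_act Thresholds drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_quadrants <- function(merged, t_abund = 0.58, t_act = 0.66) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_quadrants() needs the ggplot2 package")
  }
  ok <- is.finite(merged$abundance_score) & is.finite(merged$activity_score)
  ggplot2::ggplot(
    merged[ok, ],
    ggplot2::aes(x = .data$abundance_score, y = .data$activity_score)
  ) +
    ggplot2::geom_bin2d(bins = 60) +
    ggplot2::geom_vline(xintercept = t_abund, linetype = "dashed", color = "firebrick") +
    ggplot2::geom_hline(yintercept = t_act, linetype = "dashed", color = "firebrick") +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "abundance score", y = "activity score") +
    ggplot2::theme_minimal()
}
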