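# ggplot2 views of the two diagnostic panels: the aggregation plot and the
# z-score density with the fitted mixture components.

#' Plot the characteristic binding profile (aggregation plot)
#'
#' Mean signal against distance from the TSS. A sharp peak near offset 0 is
#' the expected signature of a promoter-binding TF and a quick quality
#' check of the input track. An optional moving average smooths the curve
#' for display only — scoring always uses the raw profile.
#'
#' @param object A `binding_profile` from [binding_profile()].
#' @param smooth Odd moving-average window width in positions (display
#'   only); `1` = no smoothing.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binding_profile <- function(object, smooth = 1, ...) {
  df <- as_tibble(object)
  if (smooth > 1) {
    k <- as.integer(smooth)
    if (k %% 2L == 0L) k <- k + 1L
    df$mean_signal <- as.numeric(stats::filter(df$mean_signal, rep(1 / k, k), sides = 2))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$mean_signal)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::labs(
      x = "distance from TSS (bp)",
      y = "mean binding signal",
      title = "Characteristic binding profile"
    ) +
    ggplot2::theme_minimal()
}

#' Plot z-score density with fitted mixture components
#'
#' Histogram of the regulatory z-scores overlaid with the two fitted
#' Gaussian components (background and target, each scaled by its mixing
#' weight) and their sum.
#'
#' @param object A `gmm2` fit from [fit_gmm2()].
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gmm2 <- function(object, bins = 50, ...) {
  z <- object$z
  grid <- seq(min(z), max(z), length.out = 512)
  curves <- tibble(
    z = rep(grid, 3),
    density = c(
      object$w[1] * dnorm(grid, object$mu[1], object$sigma[1]),
      object$w[2] * dnorm(grid, object$mu[2], object$sigma[2]),
      gmm2_density(object, grid)
    ),
    component = rep(c("background", "target", "mixture"), each = length(grid))
  )
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble(z = z),
      ggplot2::aes(x = .data$z, y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey85", color = "grey70"
    ) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$z, y = .data$density, color = .data$component)
    ) +
    ggplot2::scale_color_manual(
      values = c(background = "firebrick", target = "forestgreen", mixture = "black")
    ) +
    ggplot2::labs(
      x = "normalized regulatory score (z)",
      y = "density",
      title = "Regulatory score distribution and fitted mixture"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
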