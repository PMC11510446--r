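#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted exposure-response model
#'
#' Data points (sized by fitting weight), the fitted median curve and the
#' 95% functional prediction band on a log potency-multiple axis. Effects
#' are shown on the change-vs-placebo scale (negative reductions).
#'
#' @param object An `effect_fit`.
#' @param level Confidence level for the band.
#' @param n_grid Points in the curve grid.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.effect_fit <- function(object, level = 0.95, n_grid = 200, ...) {
  grid <- exp(seq(log(min(object$x)), log(max(object$x)),
                  length.out = n_grid))
  band <- predict_bounds(object, grid, level = level)
  pts <- tibble::tibble(x = object$x, y = -object$y, w = object$weights)
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$x, ymin = -.data$upr, ymax = -.data$lwr),
      fill = "grey80"
    ) +
    ggplot2::geom_line(
      data = band, ggplot2::aes(x = .data$x, y = -.data$fit),
      colour = "steelblue", linewidth = 1
    ) +
    ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$x, y = .data$y, size = .data$w),
      alpha = 0.7, show.legend = FALSE
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "potency multiple (fold nEC50)",
      y = "change vs placebo",
      title = sprintf("%s exposure-response fit", object$family)
    ) +
    ggplot2::theme_minimal()
}

#' Plot potency multiples against treatment effects per assay format
#'
#' One panel per assay format: median treatment effect (with 90% credible
#' range) against the potency multiple, for a single endpoint and exposure
#' metric.
#'
#' @param translation Table from [build_translation_table()].
#' @param endpoint Endpoint to plot (default first present).
#' @param metric Exposure metric (default `"cavg"`).
#' @return A ggplot object.
#' @export
plot_translation <- function(translation,
                             endpoint = unique(translation$endpoint)[1],
                             metric = "cavg") {
  dat <- translation |>
    dplyr::filter(.data$endpoint == !!endpoint, .data$metric == !!metric)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fold, y = .data$median_change,
                                    colour = .data$drug)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$cred_low, ymax = .data$cred_high),
      width = 0, alpha = 0.5
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~format) +
    ggplot2::labs(x = sprintf("%s / nEC50 (fold)", toupper(metric)),
                  y = "change vs placebo", colour = NULL,
                  title = endpoint) +
    ggplot2::theme_minimal()
}

#' Plot assay-format correlation strengths
#'
#' Bar chart of Spearman r per format, metric and endpoint, with the
#' inclusion threshold marked.
#'
#' @param ranking Table from [rank_assays()].
#' @param r_threshold Threshold line (default 0.75).
#' @return A ggplot object.
#' @export
plot_ranking <- function(ranking, r_threshold = 0.75) {
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = stats::reorder(.data$format, abs(.data$r)),
                               y = abs(.data$r), fill = .data$included)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = r_threshold, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::facet_grid(metric ~ endpoint) +
    ggplot2::labs(x = NULL, y = "|Spearman r|", fill = "included") +
    ggplot2::theme_minimal()
}
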