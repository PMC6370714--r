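#' Plot an intensity channel with optional ROI outlines
#'
#' @param image numeric matrix or [multichannel_image()].
#' @param channel channel name for multi-channel input.
#' @param labelmap optional label map; ROI centroids are marked.
#' @return a ggplot object.
#' @export
plot_channel <- function(image, channel = NULL, labelmap = NULL) {
  x <- if (inherits(image, "mcimage"))
    get_channel(image, channel %||% names(image$channels)[1]) else image
  df <- tidyr::expand_grid(row = seq_len(nrow(x)), col = seq_len(ncol(x)))
  df$value <- x[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "AU") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (!is.null(labelmap) && max(labelmap) > 0) {
    cent <- region_properties(labelmap, x)
    p <- p + ggplot2::geom_point(
      data = cent, inherit.aes = FALSE, shape = 1, colour = "red",
      ggplot2::aes(x = .data$centroid_col, y = .data$centroid_row))
  }
  p
}

#' Plot a growth curve (mean compact area and fraction per day)
#'
#' @param summary a [growth_curve()] table.
#' @return a ggplot object showing mean +/- SD compact area over DiV.
#' @export
plot_growth_curve <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$div,
                                        y = .data$mean_compact_area)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_compact_area - .data$sd_compact_area,
      ymax = .data$mean_compact_area + .data$sd_compact_area),
      alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "days in vitro", y = "compact spheroid area (px)") +
    ggplot2::theme_minimal()
}

#' Plot a rim-width sensitivity sweep
#'
#' @param sweep a [rim_width_sweep()] table.
#' @return a ggplot object of percent-brighter versus rim width.
#' @export
plot_rim_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$rim_width,
                                      y = .data$percent_brighter)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "rim width (px)", y = "rim brighter than core (%)") +
    ggplot2::theme_minimal()
}
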