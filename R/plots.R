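#' Plot a sector distribution
#'
#' Tile map of the 3 x 3 posterior-pole grid with counts and percentages,
#' oriented as the en-face image (superior at the top).
#'
#' @param object a [compute_distribution()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sector_distribution
#' @export
autoplot.sector_distribution <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  df$lab <- sprintf("%s\n%d (%.0f%%)", df$sector, df$count,
                    round_half_away(df$percentage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_col, y = .data$cell_row,
                                   fill = .data$percentage)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$lab), size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 name = "% of marks") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "SPCA entry sites per 4 x 4 mm sector") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot per-B-scan Dice coefficients
#'
#' @param object a [dice_report()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot dice_report
#' @export
autoplot.dice_report <- function(object, ...) {
  ggplot2::ggplot(object$per_bscan,
                  ggplot2::aes(x = .data$bscan, y = .data$mean_dc)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "B-scan", y = "mean Dice coefficient",
                  title = sprintf("%s agreement: %.4f (SD %.4f)",
                                  object$boundary, object$mean,
                                  ifelse(is.na(object$sd), 0, object$sd))) +
    ggplot2::theme_minimal()
}

#' Histogram of per-eye agreement correlations
#'
#' @param object an [agreement_analysis()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  ggplot2::ggplot(object$per_eye, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 1,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$median_r, linetype = 2) +
    ggplot2::labs(x = "Pearson r", y = "eyes",
                  title = sprintf("%s-correlation: median %.4f (%s)",
                                  object$mode, object$median_r,
                                  object$label)) +
    ggplot2::theme_minimal()
}

#' Plot a B-scan with overlaid boundaries
#'
#' @param volume an [oct_volume()].
#' @param segmentation a [segment_volume()] result (optional).
#' @param index B-scan index.
#' @return a ggplot.
#' @export
plot_bscan <- function(volume, segmentation = NULL, index = 1) {
  m <- get_bscan(volume, index)
  df <- tidyr::expand_grid(z = seq_len(nrow(m)) - 1, y = seq_len(ncol(m)) - 1)
  df$intensity <- as.numeric(m)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$z)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (px)", y = "depth (px)") +
    ggplot2::theme_minimal()
  if (!is.null(segmentation)) {
    bd <- tibble::tibble(
      y = rep(seq_len(nrow(segmentation$cib$depth)) - 1, 2),
      z = c(segmentation$cib$depth[, index], segmentation$cob$depth[, index]),
      boundary = rep(c("CIB", "COB"),
                     each = nrow(segmentation$cib$depth))
    )
    p <- p + ggplot2::geom_line(data = bd,
                                ggplot2::aes(colour = .data$boundary),
                                linewidth = 0.4) +
      ggplot2::scale_colour_manual(values = c(CIB = "yellow", COB = "red"))
  }
  p
}

#' Plot an en-face image
#'
#' @param image numeric matrix (lateral y rows, B-scan x columns).
#' @param title optional title.
#' @return a ggplot.
#' @export
plot_enface <- function(image, title = NULL) {
  df <- tidyr::expand_grid(y = seq_len(nrow(image)) - 1,
                           x = seq_len(ncol(image)) - 1)
  df$intensity <- as.numeric(image)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "B-scan axis", y = "lateral axis", title = title) +
    ggplot2::theme_minimal()
}
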