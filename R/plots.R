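# ggplot2 visualizations: density heatmaps, detection overlays, training
# curves. All return ggplot objects so callers can theme/compose freely.

#' Plot a density map as a heatmap
#'
#' @param map a `density_map`.
#' @return a ggplot object (viridis-filled raster; y points down, image
#'   convention).
#' @export
plot_density_map <- function(map) {
  m <- unclass(map)
  df <- tibble(
    x = rep(seq_len(ncol(m)) - 1, each = nrow(m)),
    y = rep(seq_len(nrow(m)) - 1, times = ncol(m)),
    density = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Predicted count: %.2f", sum(m)),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_density_map
#' @param object,x a `density_map` / `stand_detections` / `stand_fit`.
#' @param ... unused.
#' @export
autoplot.density_map <- function(object, ...) plot_density_map(object)

#' Overlay detections on a field image
#'
#' @param image a `field_image`.
#' @param detections a `stand_detections` tibble (from [detect_stands()]).
#' @return a ggplot object with the image, detection boxes and centers.
#' @export
plot_detections <- function(image, detections) {
  rgb_raster <- grDevices::rgb(image$pixels[, , 1] / 255,
                               image$pixels[, , 2] / 255,
                               image$pixels[, , 3] / 255)
  dim(rgb_raster) <- dim(image$pixels)[1:2]
  ggplot2::ggplot() +
    ggplot2::annotation_raster(rgb_raster, xmin = 0, xmax = image$width,
                               ymin = -image$height, ymax = 0) +
    ggplot2::geom_rect(data = as_tibble(detections),
                       ggplot2::aes(xmin = .data$x1, xmax = .data$x2,
                                    ymin = -.data$y2, ymax = -.data$y1),
                       color = "yellow", fill = NA, linewidth = 0.4) +
    ggplot2::geom_point(data = as_tibble(detections),
                        ggplot2::aes(x = .data$cx, y = -.data$cy),
                        color = "red", size = 0.8) +
    ggplot2::coord_fixed(xlim = c(0, image$width), ylim = c(-image$height, 0),
                         expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @rdname train_network
#' @param object a `stand_fit`.
#' @export
autoplot.stand_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "training loss (log scale)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
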