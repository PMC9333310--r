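#' Geometry-adaptive kernel bandwidth policy
#'
#' In crowded scenes the apparent plant size tracks the local planting
#' density, so each annotated center gets a Gaussian whose standard
#' deviation is proportional to the mean distance to its `k` nearest
#' annotated neighbours: `sigma_i = beta * mean_knn_dist_i`. Images with too
#' few points for a k-NN estimate fall back to a fixed bandwidth, and the
#' result is floored so coincident points never produce a degenerate kernel.
#'
#' @param k number of nearest neighbours used for the distance estimate.
#' @param beta unitless multiplier applied to the mean k-NN distance.
#' @param fallback_sigma bandwidth in pixels used when fewer than `k + 1`
#'   points are present.
#' @param min_sigma lower floor on the bandwidth, pixels.
#' @return a `sigma_policy` list.
#' @export
sigma_policy <- function(k = 3L, beta = 0.3, fallback_sigma = 15, min_sigma = 1) {
  if (k < 1) abort("`k` must be >= 1.")
  if (beta <= 0) abort("`beta` must be > 0.")
  if (fallback_sigma <= 0) abort("`fallback_sigma` must be > 0.")
  structure(list(k = as.integer(k), beta = beta,
                 fallback_sigma = fallback_sigma, min_sigma = min_sigma),
            class = "sigma_policy")
}

#' Mean distance to the k nearest neighbouring points
#'
#' @param points a data frame with columns `x`, `y` (0-based pixels).
#' @param index 1-based index of the query point.
#' @param k number of neighbours.
#' @return mean Euclidean distance to the `k` nearest other points, or
#'   `NA_real_` when fewer than `k + 1` points exist (the fallback signal —
#'   not an error).
#' @export
knn_mean_distance <- function(points, index, k = 3L) {
  n <- nrow(points)
  if (index < 1 || index > n) abort(sprintf("`index` must be in [1, %d].", n))
  if (n < k + 1) return(NA_real_)
  d <- sqrt((points$x - points$x[index])^2 + (points$y - points$y[index])^2)
  mean(sort(d[-index], partial = k)[seq_len(k)])
}

#' Adaptive Gaussian bandwidth for one annotated point
#'
#' @inheritParams knn_mean_distance
#' @param policy a [sigma_policy()].
#' @return bandwidth in pixels, always `>= policy$min_sigma`.
#' @export
adaptive_sigma <- function(points, index, policy = sigma_policy()) {
  d <- knn_mean_distance(points, index, policy$k)
  s <- if (is.na(d)) policy$fallback_sigma else policy$beta * d
  max(s, policy$min_sigma)
}

#' Render a ground-truth density map from point annotations
#'
#' Each annotated center contributes a discretized Gaussian kernel centered
#' at its rounded pixel, truncated at `3 sigma` and renormalized to unit
#' mass after clipping to the map, so the map integrates to the number of
#' annotated plants even when points sit at the image border.
#'
#' @param annotations a [point_annotations] object (or data frame with `x`,
#'   `y` in 0-based pixels).
#' @param height,width dimensions of the map in pixels.
#' @param policy a [sigma_policy()] controlling per-point bandwidths.
#' @return a `density_map`: an `height x width` numeric matrix, all values
#'   `>= 0`, `sum(map) == nrow(annotations)` to within `1e-3` per point.
#' @export
render_density_map <- function(annotations, height, width, policy = sigma_policy()) {
  if (nrow(annotations) > 0) {
    bad <- which(annotations$x < 0 | annotations$x >= width |
                 annotations$y < 0 | annotations$y >= height)
    if (length(bad) > 0) {
      abort(sprintf("Annotation point(s) outside the %d x %d map: index %s.",
                    height, width, paste(bad, collapse = ", ")))
    }
  }
  map <- matrix(0, nrow = height, ncol = width)
  for (i in seq_len(nrow(annotations))) {
    s <- adaptive_sigma(annotations, i, policy)
    cx <- round(annotations$x[i])  # 0-based column
    cy <- round(annotations$y[i])  # 0-based row
    r <- ceiling(3 * s)
    rows <- max(0, cy - r):min(height - 1, cy + r)
    cols <- max(0, cx - r):min(width - 1, cx + r)
    g <- exp(-(outer((rows - cy)^2, (cols - cx)^2, `+`)) / (2 * s^2))
    g[outer((rows - cy)^2, (cols - cx)^2, `+`) > r^2] <- 0
    map[rows + 1, cols + 1] <- map[rows + 1, cols + 1] + g / sum(g)
  }
  density_map(map)
}

#' @rdname render_density_map
#' @param values a non-negative numeric matrix (plants per pixel).
#' @export
density_map <- function(values) {
  if (!is.matrix(values) || any(values < 0)) {
    abort("A density map is a numeric matrix with all values >= 0.")
  }
  structure(values, class = c("density_map", "matrix", "array"))
}

#' Total count carried by a density map
#'
#' The integral of the map: the (real-valued) number of plants. Rounding to
#' an integer is left to the reporting layer.
#'
#' @param map a `density_map` (any numeric matrix works).
#' @return the sum of all pixel values.
#' @export
count_from_density <- function(map) sum(map)

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d px, count = %.3f\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Read/write density maps as plain-text TSV matrices
#'
#' Single-channel maps are persisted as tab-separated numeric text (one row
#' per pixel row), a portable plain-text stand-in for binary array formats.
#'
#' @param map a `density_map`.
#' @param path file path.
#' @return `path` (write) or a `density_map` (read).
#' @export
write_density_map <- function(map, path) {
  utils::write.table(unclass(map), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_density_map
#' @export
read_density_map <- function(path) {
  density_map(as.matrix(utils::read.table(path, sep = "\t", header = FALSE)))
}

#' Export a density map as an 8-bit PNG heatmap
#'
#' Linear ramp from 0 to `max(map)`; for visual inspection only (the PNG is
#' not a faithful numeric container).
#'
#' @param map a `density_map`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_density_heatmap <- function(map, path) {
  m <- unclass(map)
  if (max(m) > 0) m <- m / max(m)
  png::writePNG(m, path)
  invisible(path)
}
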