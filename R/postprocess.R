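# Density-map post-processing: threshold -> peaks -> boxes -> NMS.
# Counting always uses the raw map's integral; detections exist for
# localization and visualization only.

#' Predicted stand count of a density map
#'
#' Alias of [count_from_density()], re-exported under the inference API's
#' name: the count is the integral of the raw (un-thresholded) map.
#'
#' @param map a `density_map`.
#' @return the real-valued count.
#' @export
predict_count <- function(map) count_from_density(map)

#' Zero out negligible density
#'
#' Values strictly below `threshold` are set to 0; values at or above it
#' are kept unchanged.
#'
#' @param map a `density_map`.
#' @param threshold non-negative density threshold (plants per pixel).
#' @return the thresholded `density_map`.
#' @export
threshold_density <- function(map, threshold) {
  if (threshold < 0) abort("`threshold` must be >= 0.")
  m <- unclass(map)
  m[m < threshold] <- 0
  density_map(m)
}

#' Find density peaks (plant centers)
#'
#' Local maxima (each pixel `>=` its 8 neighbours) with value `>=
#' min_value` are collected, sorted by decreasing value with ties broken in
#' row-major order, and retained greedily subject to a mutual Euclidean
#' separation of at least `min_distance` pixels.
#'
#' @param map a `density_map`.
#' @param min_distance minimum separation between retained peaks, pixels.
#' @param min_value minimum density at a peak (must be `> 0` to exclude
#'   flat zero background).
#' @return a tibble with 0-based columns `x`, `y` and the peak `value`.
#' @export
find_peaks <- function(map, min_distance = 10, min_value = 1e-3) {
  if (min_distance < 1) abort("`min_distance` must be >= 1.")
  m <- unclass(map)
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  is_max <- matrix(TRUE, h, w)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (m >= pad[2:(h + 1) + di, 2:(w + 1) + dj])
  }
  cand <- which(is_max & m >= min_value, arr.ind = TRUE)
  if (nrow(cand) == 0) return(tibble(x = numeric(), y = numeric(), value = numeric()))
  v <- m[cand]
  x <- cand[, 2] - 1; y <- cand[, 1] - 1
  ord <- order(-v, y, x)  # value desc, ties row-major
  x <- x[ord]; y <- y[ord]; v <- v[ord]
  keep <- integer(0)
  for (i in seq_along(x)) {
    if (length(keep) == 0 ||
        all((x[keep] - x[i])^2 + (y[keep] - y[i])^2 >= min_distance^2)) {
      keep <- c(keep, i)
    }
  }
  tibble(x = x[keep], y = y[keep], value = v[keep])
}

#' Draw bounding boxes around peaks
#'
#' A half-open integer box of side `box_size` is centered on each peak and
#' clipped to the image; the detection score is the density at the peak.
#'
#' @param peaks a tibble with columns `x`, `y` (0-based peak coordinates).
#' @param box_size box side, pixels.
#' @param image_h,image_w image bounds for clipping.
#' @param map the density map scores are read from (optional: if missing,
#'   a `value` column on `peaks` is used, else scores are `NA`).
#' @return a `stand_detections` tibble: `x1, y1, x2, y2, cx, cy, score`
#'   (boxes half-open: a pixel `p` is inside iff `x1 <= p < x2`).
#' @export
peaks_to_boxes <- function(peaks, box_size = 40, image_h, image_w, map = NULL) {
  if (box_size < 1) abort("`box_size` must be >= 1.")
  if (nrow(peaks) == 0) {
    return(stand_detections(tibble(x1 = numeric(), y1 = numeric(),
                                   x2 = numeric(), y2 = numeric(),
                                   cx = numeric(), cy = numeric(),
                                   score = numeric())))
  }
  x1 <- pmax(0, floor(peaks$x - box_size / 2))
  y1 <- pmax(0, floor(peaks$y - box_size / 2))
  x2 <- pmin(image_w, floor(peaks$x - box_size / 2) + box_size)
  y2 <- pmin(image_h, floor(peaks$y - box_size / 2) + box_size)
  score <- if (!is.null(map)) {
    unclass(map)[cbind(round(peaks$y) + 1, round(peaks$x) + 1)]
  } else if ("value" %in% names(peaks)) peaks$value else NA_real_
  stand_detections(tibble(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                          cx = peaks$x, cy = peaks$y, score = score))
}

stand_detections <- function(df) {
  class(df) <- c("stand_detections", class(df))
  df
}

#' Intersection-over-union of half-open boxes
#'
#' @param a,b boxes as `c(x1, y1, x2, y2)` or single-row data frames.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  take <- function(z) {
    if (all(c("x1", "y1", "x2", "y2") %in% names(z))) {
      as.numeric(z[c("x1", "y1", "x2", "y2")])
    } else as.numeric(z)[1:4]
  }
  a <- take(a)
  b <- take(b)
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Greedy non-maximum suppression
#'
#' Detections are sorted by decreasing score (ties broken in row-major
#' center order); a detection is kept iff its IoU with every already-kept
#' detection is `<= iou_threshold`.
#'
#' @param detections a `stand_detections` tibble.
#' @param iou_threshold overlap ceiling in `[0, 1]`.
#' @return the retained `stand_detections`.
#' @export
non_max_suppression <- function(detections, iou_threshold = 0.3) {
  if (iou_threshold < 0 || iou_threshold > 1) abort("`iou_threshold` must be in [0, 1].")
  n <- nrow(detections)
  if (n <= 1) return(detections)
  ord <- order(-detections$score, detections$cy, detections$cx)
  d <- detections[ord, ]
  keep <- logical(n)
  kept <- integer(0)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (j in kept) {
      if (box_iou(c(d$x1[i], d$y1[i], d$x2[i], d$y2[i]),
                  c(d$x1[j], d$y1[j], d$x2[j], d$y2[j])) > iou_threshold) {
        ok <- FALSE; break
      }
    }
    if (ok) { keep[i] <- TRUE; kept <- c(kept, i) }
  }
  d[keep, ]
}

#' Count and localize stands from a predicted density map
#'
#' Composes the four post-processing steps — thresholding, peak finding,
#' box drawing, non-maximum suppression — and reports the stand count as
#' the integral of the *raw* map (post-processing affects localization
#' only, never the count).
#'
#' @param map a `density_map`.
#' @param threshold density threshold for step 1.
#' @param min_distance minimum peak separation, pixels.
#' @param min_value minimum density at a peak (defaults to `threshold`).
#' @param box_size detection box side, pixels.
#' @param iou_threshold NMS overlap ceiling.
#' @return a list: `count` (real), `detections` (`stand_detections`).
#' @export
detect_stands <- function(map, threshold = 1e-3, min_distance = 10,
                          min_value = NULL, box_size = 40,
                          iou_threshold = 0.3) {
  min_value <- min_value %||% max(threshold, .Machine$double.eps)
  thr <- threshold_density(map, threshold)
  peaks <- find_peaks(thr, min_distance = min_distance, min_value = min_value)
  det <- peaks_to_boxes(peaks, box_size = box_size,
                        image_h = nrow(map), image_w = ncol(map), map = map)
  det <- non_max_suppression(det, iou_threshold)
  list(count = predict_count(map), detections = det)
}

#' Export detections as TSV or LabelMe JSON rectangles
#'
#' @param detections a `stand_detections` tibble.
#' @param path output path (`.tsv` or `.json`).
#' @param image_id image identifier recorded in the output.
#' @param image_h,image_w image dimensions for the JSON header.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path, image_id = "image",
                             image_h = NULL, image_w = NULL) {
  if (grepl("\\.json$", path)) {
    shapes <- purrr::pmap(detections[c("x1", "y1", "x2", "y2")],
                          function(x1, y1, x2, y2) {
      list(label = "plant", points = list(c(x1, y1), c(x2, y2)),
           group_id = NULL, shape_type = "rectangle",
           flags = setNames(list(), character()))
    })
    doc <- list(version = "5.0.0", flags = setNames(list(), character()),
                shapes = shapes, imagePath = paste0(image_id, ".png"),
                imageData = NULL, imageHeight = image_h, imageWidth = image_w)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null", digits = NA)
  } else {
    out <- dplyr::mutate(as_tibble(detections), image_id = image_id,
                         .before = 1)
    readr::write_tsv(out, path)
  }
  invisible(path)
}
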