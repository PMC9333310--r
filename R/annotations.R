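#' Point annotations of plant centers
#'
#' A `point_annotations` object is a tibble with numeric columns `x` and `y`
#' holding 0-based pixel coordinates (`x` = column, `y` = row), carrying the
#' source image id and, when known, the image dimensions as attributes. The
#' convention is shared by every module: density rendering, augmentation and
#' post-processing all speak 0-based `(x, y)`.
#'
#' @param x,y numeric vectors of equal length; 0-based pixel coordinates.
#' @param image_id identifier of the source image (scalar character).
#' @param image_width,image_height image dimensions in pixels, or `NULL` if
#'   unknown. When given, every point must satisfy `0 <= x < width`,
#'   `0 <= y < height`.
#' @return a tibble of class `point_annotations` with columns `x`, `y`.
#' @examples
#' a <- point_annotations(c(10, 20), c(5, 7), image_id = "img1",
#'                        image_width = 64, image_height = 48)
#' n_points(a)
#' @export
point_annotations <- function(x = numeric(), y = numeric(), image_id = NA_character_,
                              image_width = NULL, image_height = NULL) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.")
  }
  out <- tibble(x = as.numeric(x), y = as.numeric(y))
  attr(out, "image_id") <- as.character(image_id)[1]
  attr(out, "image_width") <- image_width
  attr(out, "image_height") <- image_height
  class(out) <- c("point_annotations", class(out))
  validate_points(out)
  out
}

validate_points <- function(a) {
  w <- attr(a, "image_width")
  h <- attr(a, "image_height")
  if (!is.null(w) && !is.null(h) && nrow(a) > 0) {
    bad <- which(a$x < 0 | a$x >= w | a$y < 0 | a$y >= h)
    if (length(bad) > 0) {
      abort(sprintf(
        "Point(s) outside image bounds (%d x %d): index %s.",
        w, h, paste(bad, collapse = ", ")))
    }
  }
  invisible(a)
}

#' @rdname point_annotations
#' @param a a `point_annotations` object (or any data frame with `x`, `y`).
#' @export
n_points <- function(a) nrow(a)

#' Read plant-center points from a LabelMe-style JSON file
#'
#' Each annotated shape contributes one point: `point` shapes are taken
#' as-is, and any polygonal shape (rectangle, polygon, ...) is reduced to the
#' centroid of its vertices, so point and box annotation dialects both yield
#' plant centers. Coordinates are 0-based pixels.
#'
#' @param path path to a LabelMe JSON file (keys `imagePath`, `imageWidth`,
#'   `imageHeight`, `shapes[].points`, `shapes[].shape_type`).
#' @return a [point_annotations] tibble; the count of annotated stands is
#'   `n_points()` of the result.
#' @seealso [write_labelme_points()]
#' @export
read_labelme_points <- function(path) {
  if (!file.exists(path)) abort(sprintf("Annotation file not found: '%s'.", path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(sprintf("Malformed JSON in '%s': %s", path, conditionMessage(e))))
  shapes <- doc$shapes %||% list()
  pts <- purrr::map(shapes, function(s) {
    p <- do.call(rbind, lapply(s$points, function(q) as.numeric(unlist(q)[1:2])))
    colMeans(p)  # identity for a single point; centroid for polygons/boxes
  })
  xy <- if (length(pts)) do.call(rbind, pts) else matrix(numeric(), ncol = 2)
  w <- doc$imageWidth %||% NULL
  h <- doc$imageHeight %||% NULL
  id <- if (!is.null(doc$imagePath)) strip_ext(basename(doc$imagePath)) else strip_ext(basename(path))
  out <- tryCatch(
    point_annotations(xy[, 1], xy[, 2], image_id = id,
                      image_width = w, image_height = h),
    error = function(e) abort(sprintf("Invalid shapes in '%s': %s", path, conditionMessage(e))))
  out
}

#' Write plant-center points as a LabelMe-style JSON file
#'
#' Points round-trip exactly: `read_labelme_points(write_labelme_points(a, p))`
#' reproduces `a`'s coordinates and count.
#'
#' @param annotations a [point_annotations] object.
#' @param path output file path.
#' @param image_path value for the `imagePath` key (defaults to
#'   `<image_id>.png`).
#' @return `path`, invisibly.
#' @export
write_labelme_points <- function(annotations, path, image_path = NULL) {
  id <- attr(annotations, "image_id") %||% NA_character_
  image_path <- image_path %||% paste0(if (is.na(id)) "image" else id, ".png")
  shapes <- purrr::pmap(list(annotations$x, annotations$y), function(x, y) {
    list(label = "plant", points = list(c(x, y)), group_id = NULL,
         shape_type = "point", flags = setNames(list(), character()))
  })
  doc <- list(
    version = "5.0.0",
    flags = setNames(list(), character()),
    shapes = shapes,
    imagePath = image_path,
    imageData = NULL,
    imageHeight = attr(annotations, "image_height"),
    imageWidth = attr(annotations, "image_width"))
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null", digits = NA)
    TRUE
  }, error = function(e) abort(sprintf("Cannot write '%s': %s", path, conditionMessage(e))))
  invisible(path)
}

strip_ext <- function(x) sub("\\.[^.]*$", "", x)

#' Load an RGB field image
#'
#' Reads a PNG or JPEG file into a `field_image`: a list with `id` (filename
#' stem), `pixels` (an `height x width x 3` array on the 0--255 scale),
#' `height` and `width`. Grayscale images are replicated across the three
#' channels; an alpha channel is dropped.
#'
#' @param path path to a PNG or JPEG file.
#' @return a `field_image` object.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("Image file not found: '%s'.", path))
  ext <- tolower(sub(".*\\.", "", path))
  px <- tryCatch({
    if (ext %in% c("png")) png::readPNG(path)
    else if (ext %in% c("jpg", "jpeg")) jpeg::readJPEG(path)
    else abort(sprintf("Unsupported image format '.%s' (PNG or JPEG expected).", ext))
  }, error = function(e) abort(sprintf("Cannot read image '%s': %s", path, conditionMessage(e))))
  field_image(px * 255, id = strip_ext(basename(path)))
}

#' @rdname load_image
#' @param pixels numeric array: `H x W` (grayscale), or `H x W x C` with C in
#'   1, 3 or 4; values on the 0--255 scale.
#' @param id image identifier.
#' @export
field_image <- function(pixels, id = "image") {
  if (length(dim(pixels)) == 2) {
    pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  } else if (length(dim(pixels)) == 3 && dim(pixels)[3] == 1) {
    pixels <- array(rep(pixels[, , 1], 3), c(dim(pixels)[1:2], 3))
  } else if (length(dim(pixels)) == 3 && dim(pixels)[3] == 4) {
    pixels <- pixels[, , 1:3, drop = FALSE]
  }
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3 || d[1] < 1 || d[2] < 1) {
    abort("`pixels` must be an H x W x 3 array with H, W >= 1.")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    abort("Pixel values must lie in [0, 255].")
  }
  structure(list(id = id, pixels = pixels, height = d[1], width = d[2]),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %s: %d x %d px\n", x$id, x$width, x$height))
  invisible(x)
}

#' Save a field image as PNG
#'
#' @param image a `field_image`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Split image identifiers into train and test sets
#'
#' Random, disjoint, exhaustive partition, deterministic for a fixed seed.
#' Either an explicit `test_count` or a `test_fraction` may be given; the
#' fraction is converted with round-half-up (e.g. 394 ids at fraction 0.2
#' give 79 test images, even though an "80/20" description of 394 images is
#' often reported as 80 test images — pass `test_count = 80` to reproduce
#' that exact split size).
#'
#' @param ids character or integer vector of image identifiers.
#' @param test_count number of ids assigned to the test set.
#' @param test_fraction alternatively, the fraction of ids for testing.
#' @param seed integer seed controlling the partition.
#' @return a list with elements `train` and `test`.
#' @export
split_dataset <- function(ids, test_count = NULL, test_fraction = NULL, seed = 1L) {
  n <- length(ids)
  if (is.null(test_count)) {
    if (is.null(test_fraction)) abort("Give either `test_count` or `test_fraction`.")
    test_count <- floor(test_fraction * n + 0.5)  # round half up
  }
  if (test_count < 0 || test_count > n) {
    abort(sprintf("`test_count` must be in [0, %d], got %s.", n, test_count))
  }
  test_idx <- withr::with_seed(seed, sample.int(n, test_count))
  list(train = ids[setdiff(seq_len(n), test_idx)], test = ids[sort(test_idx)])
}
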