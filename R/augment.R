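#' Configuration for multi-scale patch augmentation
#'
#' Training data is a multi-scale pyramid of each image (scales 0.4--1.3 in
#' steps of 0.1 by default), from which fixed-size patches are cropped at
#' random locations, randomly mirrored, and perturbed with additive Gaussian
#' pixel noise.
#'
#' @param scales positive resize ratios, one pyramid level each.
#' @param patch_size side of the square training patches, pixels.
#' @param crops_per_level random crops taken from every pyramid level.
#' @param flip_probability probability of a horizontal mirror per patch.
#' @param noise_std_range range (low, high) the per-patch noise standard
#'   deviation is drawn from, on the 0--255 intensity scale.
#' @param seed integer seed for the whole augmentation pass.
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(scales = seq(0.4, 1.3, by = 0.1),
                                patch_size = 300L,
                                crops_per_level = 30L,
                                flip_probability = 0.5,
                                noise_std_range = c(0, 5),
                                seed = 1L) {
  if (length(scales) < 1 || any(scales <= 0)) abort("`scales` must be positive.")
  if (patch_size < 1) abort("`patch_size` must be >= 1.")
  if (crops_per_level < 0) abort("`crops_per_level` must be >= 0.")
  if (flip_probability < 0 || flip_probability > 1) abort("`flip_probability` must be in [0, 1].")
  if (noise_std_range[1] < 0 || noise_std_range[2] < noise_std_range[1]) {
    abort("`noise_std_range` must satisfy 0 <= low <= high.")
  }
  structure(list(scales = scales, patch_size = as.integer(patch_size),
                 crops_per_level = as.integer(crops_per_level),
                 flip_probability = flip_probability,
                 noise_std_range = noise_std_range, seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Build the multi-scale pyramid of an annotated image
#'
#' One level per scale: the image is resized by bilinear interpolation and
#' the point coordinates are multiplied by the same scale, keeping only
#' points that remain inside the resized frame.
#'
#' @param image a `field_image`.
#' @param annotations a [point_annotations] object for that image.
#' @param scales positive resize ratios.
#' @return a list of levels, each `list(image, annotations, scale)`.
#' @export
build_scale_pyramid <- function(image, annotations,
                                scales = seq(0.4, 1.3, by = 0.1)) {
  if (any(scales <= 0)) abort("`scales` must be > 0.")
  purrr::map(scales, function(s) {
    if (isTRUE(all.equal(s, 1))) {
      img <- image
    } else {
      nh <- max(1L, as.integer(round(image$height * s)))
      nw <- max(1L, as.integer(round(image$width * s)))
      img <- field_image(resize_bilinear(image$pixels, nh, nw), id = image$id)
    }
    x <- annotations$x * s
    y <- annotations$y * s
    keep <- x >= 0 & x < img$width & y >= 0 & y < img$height
    ann <- point_annotations(x[keep], y[keep],
                             image_id = attr(annotations, "image_id"),
                             image_width = img$width, image_height = img$height)
    list(image = img, annotations = ann, scale = s)
  })
}

# Bilinear resize through EBImage (which stores images x-major, hence the
# transposes on the way in and out).
resize_bilinear <- function(pixels, new_h, new_w) {
  eb <- EBImage::Image(aperm(pixels / 255, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(eb, w = new_w, h = new_h, filter = "bilinear")
  px <- aperm(EBImage::imageData(out), c(2, 1, 3)) * 255
  pmin(pmax(px, 0), 255)
}

#' Crop a random training patch from a pyramid level
#'
#' The crop offset is uniform over all valid positions; points inside the
#' half-open crop window are retained and re-expressed in patch coordinates,
#' and the patch's ground-truth density is rendered from those transformed
#' points (rather than cropped from a full-image map) so border kernels
#' renormalize correctly. Images smaller than the patch are zero-padded
#' bottom-right first, so extreme pyramid scales never drop data.
#'
#' @param level a pyramid level: `list(image, annotations, scale)`.
#' @param patch_size patch side, pixels.
#' @param policy [sigma_policy()] for the patch density map.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param offset optional forced `(x0, y0)` crop offset (0-based), mainly
#'   for tests.
#' @return a `training_patch`: `list(pixels, points, density, provenance)`.
#' @export
random_crop <- function(level, patch_size = 300L, policy = sigma_policy(),
                        seed = NULL, offset = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed, random_crop(level, patch_size, policy, offset = offset)))
  img <- level$image
  px <- img$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  if (h < patch_size || w < patch_size) {
    padded <- array(0, c(max(h, patch_size), max(w, patch_size), 3))
    padded[seq_len(h), seq_len(w), ] <- px
    px <- padded
    h <- dim(px)[1]; w <- dim(px)[2]
  }
  if (is.null(offset)) {
    x0 <- sample.int(w - patch_size + 1L, 1L) - 1L
    y0 <- sample.int(h - patch_size + 1L, 1L) - 1L
  } else {
    x0 <- offset[1]; y0 <- offset[2]
  }
  ann <- level$annotations
  keep <- ann$x >= x0 & ann$x < x0 + patch_size &
          ann$y >= y0 & ann$y < y0 + patch_size
  pts <- point_annotations(ann$x[keep] - x0, ann$y[keep] - y0,
                           image_id = attr(ann, "image_id"),
                           image_width = patch_size, image_height = patch_size)
  patch_px <- px[y0 + seq_len(patch_size), x0 + seq_len(patch_size), , drop = FALSE]
  training_patch(
    pixels = patch_px, points = pts,
    density = render_density_map(pts, patch_size, patch_size, policy),
    provenance = list(source_id = img$id, scale = level$scale,
                      offset = c(x0, y0), flipped = FALSE, noise_std = 0))
}

training_patch <- function(pixels, points, density, provenance) {
  structure(list(pixels = pixels, points = points, density = density,
                 provenance = provenance),
            class = "training_patch")
}

#' Mirror a training patch horizontally
#'
#' Columns are reversed; a point `(x, y)` maps to `(width - 1 - x, y)`; the
#' density map is mirrored the same way, so the count is preserved exactly
#' and flipping twice is the identity. Continuous coordinates in the outer
#' half of the last pixel column (`x > width - 1`) would mirror to negative
#' values and are clamped to 0 — a sub-pixel shift that keeps every point
#' in bounds.
#'
#' @param patch a `training_patch`.
#' @return the mirrored `training_patch`.
#' @export
horizontal_flip <- function(patch) {
  w <- dim(patch$pixels)[2]
  pts <- patch$points
  flipped <- point_annotations(pmax(0, w - 1 - pts$x), pts$y,
                               image_id = attr(pts, "image_id"),
                               image_width = attr(pts, "image_width"),
                               image_height = attr(pts, "image_height"))
  prov <- patch$provenance
  prov$flipped <- !isTRUE(prov$flipped)
  training_patch(
    pixels = patch$pixels[, w:1, , drop = FALSE],
    points = flipped,
    density = density_map(unclass(patch$density)[, w:1, drop = FALSE]),
    provenance = prov)
}

#' Add clamped Gaussian pixel noise to a patch
#'
#' Zero-mean i.i.d. Gaussian noise is added per channel and the result is
#' clamped to the 0--255 range; annotations and density are untouched.
#'
#' @param patch a `training_patch`.
#' @param std noise standard deviation on the 0--255 scale (`>= 0`).
#' @param seed optional integer seed.
#' @return the noised `training_patch`.
#' @export
add_gaussian_noise <- function(patch, std, seed = NULL) {
  if (std < 0) abort("`std` must be >= 0.")
  if (!is.null(seed)) return(withr::with_seed(seed, add_gaussian_noise(patch, std)))
  if (std > 0) {
    noise <- array(rnorm(length(patch$pixels), 0, std), dim(patch$pixels))
    patch$pixels <- pmin(pmax(patch$pixels + noise, 0), 255)
  }
  patch$provenance$noise_std <- std
  patch
}

#' Build the full augmented training set
#'
#' For every image and every pyramid scale, `crops_per_level` random patches
#' are cut, each mirrored with probability `flip_probability` and noised
#' with a standard deviation drawn uniformly from `noise_std_range`. The
#' result has exactly `n_images * n_scales * crops_per_level` patches and is
#' fully reproducible from `config$seed`.
#'
#' @param dataset a list of annotated images, each
#'   `list(image = field_image, annotations = point_annotations)`.
#' @param config an [augmentation_config()].
#' @param policy [sigma_policy()] for patch density maps.
#' @return a list of `training_patch` objects.
#' @export
build_training_set <- function(dataset, config = augmentation_config(),
                               policy = sigma_policy()) {
  if (length(dataset) == 0) {
    warn("Empty dataset: returning an empty training set.")
    return(list())
  }
  withr::with_seed(config$seed, {
    patches <- purrr::map(dataset, function(item) {
      pyr <- build_scale_pyramid(item$image, item$annotations, config$scales)
      purrr::map(pyr, function(level) {
        purrr::map(seq_len(config$crops_per_level), function(i) {
          p <- random_crop(level, config$patch_size, policy)
          if (runif(1) < config$flip_probability) p <- horizontal_flip(p)
          std <- runif(1, config$noise_std_range[1], config$noise_std_range[2])
          add_gaussian_noise(p, std)
        })
      })
    })
    purrr::flatten(purrr::flatten(patches))
  })
}

#' Persist a patch set as PNG files plus a TSV manifest
#'
#' @param patches a list of `training_patch` objects.
#' @param dir output directory (created if missing).
#' @return the manifest tibble (patch id, source id, scale, offset, flip,
#'   noise std, count), invisibly written to `manifest.tsv`.
#' @export
write_patch_set <- function(patches, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::imap(patches, function(p, i) {
    id <- sprintf("patch_%05d", i)
    png::writePNG(p$pixels / 255, file.path(dir, paste0(id, ".png")))
    write_density_map(p$density, file.path(dir, paste0(id, "_density.tsv")))
    pr <- p$provenance
    tibble(patch_id = id, source_id = pr$source_id, scale = pr$scale,
           offset_x = pr$offset[1], offset_y = pr$offset[2],
           flipped = isTRUE(pr$flipped), noise_std = pr$noise_std,
           count = n_points(p$points))
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Load a patch set written by [write_patch_set()]
#'
#' @param dir directory containing `manifest.tsv` and the patch files.
#' @return a list of `training_patch` objects (points are not recoverable
#'   from disk and are left empty; density and pixels round-trip).
#' @export
read_patch_set <- function(dir) {
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                              show_col_types = FALSE)
  purrr::pmap(manifest, function(patch_id, source_id, scale, offset_x,
                                 offset_y, flipped, noise_std, count) {
    px <- png::readPNG(file.path(dir, paste0(patch_id, ".png"))) * 255
    den <- read_density_map(file.path(dir, paste0(patch_id, "_density.tsv")))
    training_patch(pixels = px, points = point_annotations(),
                   density = den,
                   provenance = list(source_id = source_id, scale = scale,
                                     offset = c(offset_x, offset_y),
                                     flipped = flipped, noise_std = noise_std))
  })
}
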