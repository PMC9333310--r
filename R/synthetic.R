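#' Synthetic field-image configuration
#'
#' Generates field-like RGB images with known plant-center annotations:
#' procedural green leaf rosettes over a textured soil background. The
#' defaults emulate the statistical structure of early-season maize stand
#' imagery: 1024 x 768 frames with 5--31 plants each (uniform by default;
#' the `"triangular"` count mode targets a mean of 15.62 plants per image,
#' the published dataset average). The growth-stage label drives difficulty
#' monotonically — later stages mean more and longer leaves and a smaller
#' center separation, i.e. more occlusion.
#'
#' @param image_size `(height, width)` in pixels.
#' @param count_range inclusive `(min, max)` plants per image.
#' @param count_distribution `"uniform"` over the range, or `"triangular"`
#'   (mode chosen so the mean is 15.62 under the default range).
#' @param stage growth stage label, one of `"VE", "V1", ..., "V6"`.
#' @param min_center_separation minimum distance between plant centers in
#'   pixels; `NULL` uses a stage-dependent default (relaxed automatically
#'   if placement keeps failing).
#' @param background list: `base_rgb` (soil color, 0--255) and `noise_amp`
#'   (low-frequency texture amplitude).
#' @param illumination_jitter multiplicative brightness range per image.
#' @param seed integer seed.
#' @return a `synthetic_field_config` list.
#' @export
synthetic_field_config <- function(image_size = c(768L, 1024L),
                                   count_range = c(5L, 31L),
                                   count_distribution = c("uniform", "triangular"),
                                   stage = "V3",
                                   min_center_separation = NULL,
                                   background = list(base_rgb = c(118, 94, 72),
                                                     noise_amp = 18),
                                   illumination_jitter = c(0.85, 1.15),
                                   seed = 1L) {
  count_distribution <- match.arg(count_distribution)
  stages <- c("VE", "V1", "V2", "V3", "V4", "V5", "V6")
  if (!stage %in% stages) abort(sprintf("`stage` must be one of %s.", paste(stages, collapse = ", ")))
  if (count_range[1] < 1 || count_range[2] < count_range[1]) {
    abort("`count_range` must satisfy 0 < min <= max.")
  }
  idx <- match(stage, stages)
  params <- stage_params(idx, image_size)
  structure(list(
    image_size = as.integer(image_size),
    count_range = as.integer(count_range),
    count_distribution = count_distribution,
    stage = stage, stage_index = idx,
    leaves = params$leaves, leaf_length = params$leaf_length,
    min_center_separation = min_center_separation %||% params$min_sep,
    background = background,
    illumination_jitter = illumination_jitter,
    seed = as.integer(seed)),
    class = "synthetic_field_config")
}

# Stage VE..V6 -> leaf count 1..6, leaf length 10..60 px, decreasing
# allowed separation (occlusion grows with stage). Separation scales with
# the frame so small desk-scale images stay feasible.
stage_params <- function(idx, image_size) {
  leaves <- c(1, 1, 2, 3, 4, 5, 6)[idx]
  leaf_length <- seq(10, 60, length.out = 7)[idx]
  base_sep <- seq(70, 22, length.out = 7)[idx]
  sep <- min(base_sep, min(image_size) / 6)
  list(leaves = leaves, leaf_length = leaf_length, min_sep = sep)
}

draw_count <- function(config) {
  lo <- config$count_range[1]; hi <- config$count_range[2]
  if (hi == lo) return(lo)
  if (config$count_distribution == "uniform") {
    return(sample(lo:hi, 1L))
  }
  # triangular on [lo, hi] with mode chosen so that the mean
  # (lo + mode + hi) / 3 matches 15.62 under the default 5..31 range
  mode_t <- max(lo, min(hi, 3 * 15.62 - lo - hi))
  u <- runif(1)
  fc <- (mode_t - lo) / (hi - lo)
  v <- if (u < fc) lo + sqrt(u * (hi - lo) * (mode_t - lo))
       else hi - sqrt((1 - u) * (hi - lo) * (hi - mode_t))
  as.integer(round(min(hi, max(lo, v))))
}

# Low-frequency soil texture: coarse Gaussian grid, bilinearly upsampled.
soil_background <- function(h, w, base_rgb, noise_amp) {
  gh <- max(2L, h %/% 64L); gw <- max(2L, w %/% 64L)
  coarse <- matrix(rnorm(gh * gw), gh, gw)
  up <- resize_matrix_bilinear(coarse, h, w)
  px <- array(0, c(h, w, 3))
  for (c in 1:3) {
    px[, , c] <- base_rgb[c] + noise_amp * up +
      matrix(rnorm(h * w, 0, 6), h, w)
  }
  pmin(pmax(px, 0), 255)
}

resize_matrix_bilinear <- function(m, h, w) {
  yi <- seq(1, nrow(m), length.out = h)
  xi <- seq(1, ncol(m), length.out = w)
  y0 <- pmin(floor(yi), nrow(m) - 1); x0 <- pmin(floor(xi), ncol(m) - 1)
  fy <- yi - y0; fx <- xi - x0
  m[y0, x0] * outer(1 - fy, 1 - fx) + m[y0 + 1, x0] * outer(fy, 1 - fx) +
    m[y0, x0 + 1] * outer(1 - fy, fx) + m[y0 + 1, x0 + 1] * outer(fy, fx)
}

# Paint one plant: a rosette of elongated ellipse leaves radiating from the
# center, plus a small bright whorl disc at the center itself.
paint_plant <- function(px, cx, cy, config, illum) {
  h <- dim(px)[1]; w <- dim(px)[2]
  n_leaves <- config$leaves
  len <- config$leaf_length * runif(1, 0.8, 1.2)
  base_green <- c(62, 132, 48) * runif(1, 0.85, 1.15) * illum
  angle0 <- runif(1, 0, 2 * pi)
  for (l in seq_len(max(1, n_leaves))) {
    theta <- angle0 + 2 * pi * (l - 1) / max(1, n_leaves) + rnorm(1, 0, 0.15)
    a <- len / 2 * runif(1, 0.85, 1.15)       # semi-major
    b <- max(1.5, a * 0.25)                   # semi-minor
    lx <- cx + 0.9 * a * cos(theta)           # leaf center offset
    ly <- cy + 0.9 * a * sin(theta)
    r <- ceiling(a) + 2
    rows <- max(0, floor(ly - r)):min(h - 1, ceiling(ly + r))
    cols <- max(0, floor(lx - r)):min(w - 1, ceiling(lx + r))
    if (length(rows) == 0 || length(cols) == 0) next
    dy <- outer(rows - ly, rep(1, length(cols)))
    dx <- outer(rep(1, length(rows)), cols - lx)
    u <- (dx * cos(theta) + dy * sin(theta)) / a
    v <- (-dx * sin(theta) + dy * cos(theta)) / b
    mask <- u^2 + v^2 <= 1
    if (!any(mask)) next
    shade <- 1 - 0.25 * abs(u[mask])          # tips slightly darker
    for (c in 1:3) {
      ch <- px[rows + 1, cols + 1, c]
      ch[mask] <- pmin(255, base_green[c] * shade + rnorm(sum(mask), 0, 4))
      px[rows + 1, cols + 1, c] <- ch
    }
  }
  # center whorl
  r0 <- max(2, config$leaf_length * 0.12)
  rows <- max(0, floor(cy - r0)):min(h - 1, ceiling(cy + r0))
  cols <- max(0, floor(cx - r0)):min(w - 1, ceiling(cx + r0))
  if (length(rows) > 0 && length(cols) > 0) {
    d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
    mask <- d2 <= r0^2
    bright <- pmin(255, base_green * 1.3)
    for (c in 1:3) {
      ch <- px[rows + 1, cols + 1, c]
      ch[mask] <- bright[c]
      px[rows + 1, cols + 1, c] <- ch
    }
  }
  px
}

#' Generate one synthetic field image with annotations
#'
#' Plant count is drawn from the configured distribution; centers are
#' placed by rejection sampling at the configured minimum separation (the
#' separation is halved, with a message, after 1000 consecutive rejections,
#' and placement errors out only if a relaxed separation still fails);
#' each plant is a procedurally drawn green rosette. Deterministic for a
#' fixed seed.
#'
#' @param config a [synthetic_field_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param count optional forced plant count (overrides the draw).
#' @return `list(image = field_image, annotations = point_annotations)`.
#' @export
generate_field_image <- function(config = synthetic_field_config(),
                                 seed = config$seed, count = NULL) {
  withr::with_seed(seed, {
    h <- config$image_size[1]; w <- config$image_size[2]
    n <- count %||% draw_count(config)
    sep <- config$min_center_separation
    margin <- min(max(4, config$leaf_length * 0.3), (min(h, w) - 2) / 4)
    centers <- matrix(numeric(), ncol = 2)
    fails <- 0L
    while (nrow(centers) < n) {
      cand <- c(runif(1, margin, w - 1 - margin), runif(1, margin, h - 1 - margin))
      ok <- nrow(centers) == 0 ||
        all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >= sep^2)
      if (ok) {
        centers <- rbind(centers, cand)
        fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= 1000L) {
          if (sep <= 2) {
            abort(sprintf("Cannot place %d plants even after relaxing separation.", n))
          }
          sep <- sep / 2
          inform(sprintf("Center placement congested: relaxing separation to %.1f px.", sep))
          fails <- 0L
        }
      }
    }
    illum <- runif(1, config$illumination_jitter[1], config$illumination_jitter[2])
    px <- soil_background(h, w, config$background$base_rgb * illum,
                          config$background$noise_amp)
    for (i in seq_len(n)) {
      px <- paint_plant(px, centers[i, 1], centers[i, 2], config, illum)
    }
    ann <- point_annotations(centers[, 1], centers[, 2],
                             image_id = sprintf("synthetic_%06d", seed %% 1000000L),
                             image_width = w, image_height = h)
    list(image = field_image(px, id = attr(ann, "image_id")), annotations = ann)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` PNG images with matching LabelMe-style JSON annotation
#' files and a TSV manifest (`id`, `image`, `annotations`, `count`,
#' `stage`). Each image uses a seed derived deterministically from `seed`.
#'
#' @param config a [synthetic_field_config()].
#' @param n_images number of images (`>= 1`).
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed.
#' @return the manifest tibble.
#' @export
generate_field_dataset <- function(config = synthetic_field_config(),
                                   n_images, out_dir, seed = config$seed) {
  if (n_images < 1) abort("`n_images` must be >= 1.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(seq_len(n_images), function(i) {
    s <- (seed + 7919L * i) %% .Machine$integer.max
    sim <- generate_field_image(config, seed = s)
    id <- sprintf("field_%04d", i)
    img_path <- file.path(out_dir, paste0(id, ".png"))
    json_path <- file.path(out_dir, paste0(id, ".json"))
    sim$image$id <- id
    attr(sim$annotations, "image_id") <- id
    save_image(sim$image, img_path)
    write_labelme_points(sim$annotations, json_path,
                         image_path = basename(img_path))
    tibble(id = id, image = basename(img_path),
           annotations = basename(json_path),
           count = n_points(sim$annotations), stage = config$stage)
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}

#' Load a dataset directory written by [generate_field_dataset()]
#'
#' @param dir dataset directory containing `manifest.tsv`.
#' @return a list of `list(image, annotations)` pairs.
#' @export
load_field_dataset <- function(dir) {
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                              show_col_types = FALSE)
  purrr::pmap(manifest[c("image", "annotations")], function(image, annotations) {
    list(image = load_image(file.path(dir, image)),
         annotations = read_labelme_points(file.path(dir, annotations)))
  })
}
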