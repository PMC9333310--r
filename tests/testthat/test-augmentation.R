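test_that("the scale pyramid has one level per scale with scaled geometry", {
  sim <- make_patch_fixture(size = 64, counts = 3, seed = 2)
  pyr <- build_scale_pyramid(sim$image, sim$annotations)
  expect_length(pyr, 10)  # 0.4, 0.5, ..., 1.3
  expect_equal(purrr::map_dbl(pyr, "scale"), seq(0.4, 1.3, by = 0.1))

  half <- build_scale_pyramid(sim$image, sim$annotations, scales = 0.5)[[1]]
  expect_equal(c(half$image$height, half$image$width), c(32, 32))
  expect_equal(half$annotations$x, sim$annotations$x * 0.5)

  ident <- build_scale_pyramid(sim$image, sim$annotations, scales = 1)[[1]]
  expect_identical(ident$image$pixels, sim$image$pixels)
  expect_equal(ident$annotations$x, sim$annotations$x)

  expect_error(build_scale_pyramid(sim$image, sim$annotations, scales = c(1, -1)),
               "scales")
})

test_that("random crops keep in-window points in patch coordinates", {
  ann <- point_annotations(c(10, 310, 150), c(20, 10, 250),
                           image_width = 600, image_height = 600)
  img <- field_image(array(100, c(600, 600, 3)), id = "t")
  level <- list(image = img, annotations = ann, scale = 1)

  corner <- random_crop(level, 300, offset = c(0, 0))
  expect_equal(corner$points$x, c(10, 150))
  expect_equal(corner$points$y, c(20, 250))

  shifted <- random_crop(level, 300, offset = c(300, 0))
  expect_equal(shifted$points$x, 10)  # 310 - 300
  expect_equal(shifted$points$y, 10)

  # undersized images are zero-padded bottom-right, keeping all points
  small <- list(image = field_image(array(50, c(200, 200, 3)), id = "s"),
                annotations = point_annotations(c(5, 190), c(5, 190),
                                                image_width = 200,
                                                image_height = 200),
                scale = 1)
  padded <- random_crop(small, 300, offset = c(0, 0))
  expect_equal(dim(padded$pixels), c(300, 300, 3))
  expect_equal(n_points(padded$points), 2)
  expect_equal(sum(padded$pixels[201:300, , ]), 0)
})

test_that("cropping never emits out-of-bounds points and conserves density", {
  sim <- make_patch_fixture(size = 40, counts = 6, seed = 9)
  level <- list(image = sim$image, annotations = sim$annotations, scale = 1)
  withr::with_seed(14, {
    for (rep in 1:1000) {
      p <- random_crop(level, 20)
      expect_true(all(p$points$x >= 0 & p$points$x < 20))
      expect_true(all(p$points$y >= 0 & p$points$y < 20))
      expect_lt(abs(sum(p$density) - n_points(p$points)),
                1e-3 * max(1, n_points(p$points)))
    }
  })
})

test_that("horizontal flip mirrors points and is an involution", {
  sim <- make_patch_fixture(size = 48, counts = 4, seed = 5)
  level <- list(image = sim$image, annotations = sim$annotations, scale = 1)
  p <- random_crop(level, 48, offset = c(0, 0))
  f <- horizontal_flip(p)
  expect_equal(sort(f$points$x), sort(pmax(0, 47 - p$points$x)))
  expect_equal(sum(f$density), sum(p$density))
  ff <- horizontal_flip(f)
  expect_identical(ff$pixels, p$pixels)
  # involution on points, up to the sub-pixel clamp at the border
  expect_lt(max(abs(sort(ff$points$x) - sort(p$points$x))), 1)
  expect_equal(sort(ff$points$y), sort(p$points$y))

  # boundary map on a 300-wide patch
  wide <- structure(list(
    pixels = array(0, c(300, 300, 3)),
    points = point_annotations(0, 5, image_width = 300, image_height = 300),
    density = density_map(matrix(0, 300, 300)),
    provenance = list(flipped = FALSE)), class = "training_patch")
  expect_equal(horizontal_flip(wide)$points$x, 299)
})

test_that("Gaussian pixel noise is clamped, seeded and correctly scaled", {
  p <- structure(list(pixels = array(128, c(80, 80, 3)),
                      points = point_annotations(),
                      density = density_map(matrix(0, 80, 80)),
                      provenance = list()), class = "training_patch")
  expect_identical(add_gaussian_noise(p, 0)$pixels, p$pixels)
  n1 <- add_gaussian_noise(p, 5, seed = 3)
  n2 <- add_gaussian_noise(p, 5, seed = 3)
  expect_identical(n1$pixels, n2$pixels)
  expect_true(all(n1$pixels >= 0 & n1$pixels <= 255))
  # folded-normal mean |X| = std * sqrt(2/pi); mid-gray base avoids clamping
  mean_abs <- mean(abs(n1$pixels - p$pixels))
  expect_equal(mean_abs, 5 * sqrt(2 / pi), tolerance = 0.05)
  expect_error(add_gaussian_noise(p, -1), "std")
})

test_that("the training set enumerates images x scales x crops deterministically", {
  sims <- lapply(1:2, function(i) make_patch_fixture(48, 3, seed = 20 + i))
  dataset <- lapply(sims, function(s) list(image = s$image, annotations = s$annotations))
  cfg <- augmentation_config(scales = c(0.8, 1), patch_size = 32,
                             crops_per_level = 3, seed = 4)
  patches <- build_training_set(dataset, cfg)
  expect_length(patches, 2 * 2 * 3)
  for (p in patches) {
    expect_lt(abs(sum(p$density) - n_points(p$points)),
              1e-3 * max(1, n_points(p$points)))
  }
  prov <- function(ps) purrr::map(ps, "provenance")
  expect_identical(prov(build_training_set(dataset, cfg)), prov(patches))

  one <- build_training_set(dataset[1],
                            augmentation_config(scales = 1, patch_size = 32,
                                                crops_per_level = 5, seed = 1))
  expect_length(one, 5)
  expect_warning(build_training_set(list(), cfg), "Empty")
})

test_that("patch sets persist to PNG + TSV and reload", {
  dir <- withr::local_tempdir()
  sim <- make_patch_fixture(48, 3, seed = 31)
  dataset <- list(list(image = sim$image, annotations = sim$annotations))
  patches <- build_training_set(dataset,
                                augmentation_config(scales = 1, patch_size = 32,
                                                    crops_per_level = 2, seed = 2))
  manifest <- write_patch_set(patches, dir)
  expect_equal(nrow(manifest), 2)
  back <- read_patch_set(dir)
  expect_length(back, 2)
  expect_equal(unclass(back[[1]]$density), unclass(patches[[1]]$density),
               ignore_attr = TRUE)
  expect_equal(back[[1]]$pixels, patches[[1]]$pixels, tolerance = 1)
})
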