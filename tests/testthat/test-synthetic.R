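test_that("generated fields respect count range, forced counts and seeds", {
  cfg <- synthetic_field_config(image_size = c(96, 128), seed = 2)
  sim <- generate_field_image(cfg, seed = 2)
  expect_s3_class(sim$image, "field_image")
  expect_true(n_points(sim$annotations) >= 5 && n_points(sim$annotations) <= 31)
  expect_true(all(sim$image$pixels >= 0 & sim$image$pixels <= 255))

  forced <- generate_field_image(cfg, seed = 3, count = 15)
  expect_equal(n_points(forced$annotations), 15)

  again <- generate_field_image(cfg, seed = 2)
  expect_identical(sim$image$pixels, again$image$pixels)
  expect_identical(sim$annotations$x, again$annotations$x)
})

test_that("plants are visibly greener than the soil background", {
  cfg <- synthetic_field_config(image_size = c(96, 96), count_range = c(4, 4),
                                stage = "V3", seed = 5)
  sim <- generate_field_image(cfg, seed = 5)
  px <- sim$image$pixels
  greenness <- px[, , 2] - (px[, , 1] + px[, , 3]) / 2
  at_plants <- mapply(function(x, y) greenness[round(y) + 1, round(x) + 1],
                      sim$annotations$x, sim$annotations$y)
  expect_gt(min(at_plants), mean(greenness))
})

test_that("generated datasets round-trip through the annotation reader", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_field_config(image_size = c(64, 64), count_range = c(2, 6),
                                stage = "V2", seed = 4)
  manifest <- generate_field_dataset(cfg, n_images = 3, out_dir = dir, seed = 4)
  expect_equal(nrow(manifest), 3)
  expect_true(all(file.exists(file.path(dir, manifest$image))))

  dataset <- load_field_dataset(dir)
  expect_length(dataset, 3)
  for (i in 1:3) {
    expect_equal(n_points(dataset[[i]]$annotations), manifest$count[i])
    # rendered densities of generated annotations conserve the count
    m <- render_density_map(dataset[[i]]$annotations, 64, 64)
    expect_lt(abs(sum(m) - manifest$count[i]), 1e-3 * manifest$count[i])
  }
})

test_that("the empirical mean count tracks the configured distribution", {
  cfg <- synthetic_field_config(image_size = c(48, 64), count_range = c(5, 31),
                                stage = "V1", seed = 1)
  counts <- vapply(1:120, function(i) {
    withr::with_seed(i, standcount:::draw_count(cfg))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 18) / 18, 0.1)  # uniform on [5, 31]: mean 18

  tri <- synthetic_field_config(image_size = c(48, 64), count_range = c(5, 31),
                                count_distribution = "triangular",
                                stage = "V1", seed = 1)
  tcounts <- vapply(1:200, function(i) {
    withr::with_seed(i, standcount:::draw_count(tri))
  }, numeric(1))
  expect_lt(abs(mean(tcounts) - 15.62) / 15.62, 0.1)
})

test_that("later growth stages pack plants more tightly (occlusion proxy)", {
  nn_dist <- function(stage, seed) {
    cfg <- synthetic_field_config(image_size = c(400, 400),
                                  count_range = c(8, 8), stage = stage,
                                  seed = seed)
    sim <- generate_field_image(cfg, seed = seed)
    d <- as.matrix(stats::dist(cbind(sim$annotations$x, sim$annotations$y)))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  v1 <- mean(vapply(1:6, function(i) nn_dist("V1", 40 + i), numeric(1)))
  v6 <- mean(vapply(1:6, function(i) nn_dist("V6", 40 + i), numeric(1)))
  expect_lt(v6, v1)
})

test_that("infeasible placement relaxes and ultimately errors", {
  cfg <- synthetic_field_config(image_size = c(40, 40), count_range = c(30, 30),
                                stage = "V1", min_center_separation = 30,
                                seed = 1)
  # 30 plants at >= 30 px separation cannot fit a 40 px frame: the generator
  # must relax (messages) and still deliver the full count
  expect_message(sim <- generate_field_image(cfg, seed = 1), "relaxing")
  expect_equal(n_points(sim$annotations), 30)
})
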