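test_that("LabelMe point files round-trip points and counts exactly", {
  tmp <- withr::local_tempfile(fileext = ".json")
  a <- point_annotations(c(10, 20, 30), c(10, 20, 30), image_id = "img",
                         image_width = 100, image_height = 100)
  write_labelme_points(a, tmp)
  b <- read_labelme_points(tmp)
  expect_equal(n_points(b), 3)
  expect_equal(b$x, a$x)
  expect_equal(b$y, a$y)

  empty <- point_annotations(image_id = "none", image_width = 10, image_height = 10)
  write_labelme_points(empty, tmp)
  expect_equal(n_points(read_labelme_points(tmp)), 0)

  # property: many random in-bounds points survive a round trip unchanged
  withr::with_seed(99, {
    big <- point_annotations(runif(1000, 0, 512), runif(1000, 0, 384),
                             image_id = "big", image_width = 512,
                             image_height = 384)
    write_labelme_points(big, tmp)
    back <- read_labelme_points(tmp)
    expect_equal(back$x, big$x)
    expect_equal(back$y, big$y)
  })
})

test_that("polygonal LabelMe shapes reduce to their centroids", {
  tmp <- withr::local_tempfile(fileext = ".json")
  doc <- list(version = "5.0.0",
              shapes = list(list(label = "plant",
                                 points = list(c(0, 0), c(10, 10)),
                                 shape_type = "rectangle")),
              imagePath = "x.png", imageHeight = 20, imageWidth = 20)
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA)
  a <- read_labelme_points(tmp)
  expect_equal(n_points(a), 1)
  expect_equal(c(a$x, a$y), c(5, 5))
})

test_that("malformed or out-of-bounds annotation files fail loudly", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", tmp)
  expect_error(read_labelme_points(tmp), "Malformed JSON")

  doc <- list(shapes = list(list(label = "p", points = list(c(50, 5)),
                                 shape_type = "point")),
              imagePath = "x.png", imageHeight = 10, imageWidth = 10)
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA)
  expect_error(read_labelme_points(tmp), "bounds")
  expect_error(read_labelme_points("does/not/exist.json"), "not found")
})

test_that("images load with recorded dimensions and channel conventions", {
  tmp <- withr::local_tempfile(fileext = ".png")
  px <- array(runif(6 * 4 * 3), c(4, 6, 3))
  png::writePNG(px, tmp)
  img <- load_image(tmp)
  expect_s3_class(img, "field_image")
  expect_equal(c(img$height, img$width), c(4, 6))
  expect_equal(img$pixels, px * 255, tolerance = 1 / 255)

  # 1x1 black pixel
  png::writePNG(array(0, c(1, 1, 3)), tmp)
  one <- load_image(tmp)
  expect_equal(as.numeric(one$pixels), c(0, 0, 0))

  # grayscale replicates into three identical channels
  png::writePNG(matrix(0.5, 3, 3), tmp)
  g <- load_image(tmp)
  expect_equal(g$pixels[, , 1], g$pixels[, , 2])
  expect_equal(g$pixels[, , 2], g$pixels[, , 3])
})

test_that("dataset splits are disjoint, exhaustive and reproducible", {
  ids <- sprintf("img%03d", 1:394)
  sp <- split_dataset(ids, test_count = 80, seed = 5)
  expect_length(sp$test, 80)
  expect_length(sp$train, 314)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)

  expect_identical(sp, split_dataset(ids, test_count = 80, seed = 5))
  sp2 <- split_dataset(ids, test_count = 80, seed = 6)
  expect_false(identical(sp$test, sp2$test))

  expect_length(split_dataset(1:10, test_count = 0, seed = 1)$test, 0)
  expect_error(split_dataset(1:10, test_count = 11, seed = 1), "test_count")

  # fraction uses round-half-up
  expect_length(split_dataset(ids, test_fraction = 0.2, seed = 1)$test, 79)
  expect_length(split_dataset(1:10, test_fraction = 0.25, seed = 1)$test, 3)

  # property: random sizes stay disjoint and exhaustive
  withr::with_seed(11, {
    for (rep in 1:25) {
      n <- sample(1:200, 1)
      tc <- sample(0:n, 1)
      s <- split_dataset(seq_len(n), test_count = tc, seed = rep)
      expect_length(s$test, tc)
      expect_setequal(c(s$train, s$test), seq_len(n))
      expect_length(intersect(s$train, s$test), 0)
    }
  })
})
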