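test_that("thresholding zeroes sub-threshold density and keeps ties", {
  m <- density_map(matrix(c(0.005, 0.02, 0.02, 0.5), 2, 2))
  expect_equal(unclass(threshold_density(m, 0)), unclass(m), ignore_attr = TRUE)
  expect_equal(sum(threshold_density(density_map(matrix(0.01, 4, 4)), 0.02)), 0)
  kept <- threshold_density(m, 0.02)
  expect_equal(sum(kept > 0), 3)  # the two 0.02 values survive (>= semantics)
})

test_that("peaks are recovered at rendered kernel centers", {
  a <- point_annotations(c(10, 30), c(10, 10))
  m <- render_density_map(a, 41, 41, sigma_policy(fallback_sigma = 2, k = 5))
  pk <- find_peaks(m, min_distance = 5, min_value = 1e-4)
  expect_equal(nrow(pk), 2)
  expect_setequal(pk$x, c(10, 30))
  expect_setequal(pk$y, c(10, 10))

  expect_equal(nrow(find_peaks(density_map(matrix(0, 10, 10)),
                               min_distance = 2, min_value = 1e-6)), 0)
})

test_that("plateaus yield one peak per separated plateau, row-major first", {
  m <- matrix(0, 20, 20)
  m[3:4, 3:4] <- 0.5        # one plateau
  m[15:16, 15:16] <- 0.5    # a second, far away
  pk <- find_peaks(density_map(m), min_distance = 5, min_value = 0.1)
  expect_equal(nrow(pk), 2)
  # first in row-major order within each plateau: (x=2, y=2) and (14, 14)
  expect_setequal(paste(pk$x, pk$y), c("2 2", "14 14"))
})

test_that("boxes center on peaks and clip to the image", {
  pk <- tibble::tibble(x = c(50, 5), y = c(50, 5), value = c(1, 2))
  det <- peaks_to_boxes(pk, box_size = 40, image_h = 100, image_w = 100)
  expect_equal(unlist(det[1, c("x1", "y1", "x2", "y2")], use.names = FALSE),
               c(30, 30, 70, 70))
  expect_equal(unlist(det[2, c("x1", "y1", "x2", "y2")], use.names = FALSE),
               c(0, 0, 25, 25))
  expect_true(all(det$cx >= det$x1 & det$cx < det$x2))
  expect_equal(nrow(peaks_to_boxes(tibble::tibble(x = numeric(), y = numeric()),
                                   40, 100, 100)), 0)
})

test_that("IoU and greedy NMS match hand arithmetic", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(1, 1, 11, 11)), 81 / 119)
  expect_equal(box_iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)

  det <- stand_detections(tibble::tibble(
    x1 = c(0, 1), y1 = c(0, 1), x2 = c(10, 11), y2 = c(10, 11),
    cx = c(5, 6), cy = c(5, 6), score = c(0.9, 0.8)))
  kept <- non_max_suppression(det, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.9)

  disjoint <- stand_detections(tibble::tibble(
    x1 = c(0, 20), y1 = c(0, 20), x2 = c(10, 30), y2 = c(10, 30),
    cx = c(5, 25), cy = c(5, 25), score = c(0.5, 0.4)))
  expect_equal(nrow(non_max_suppression(disjoint, 0.3)), 2)
})

test_that("NMS equals the brute-force oracle on random box sets", {
  withr::with_seed(17, {
    x1 <- runif(200, 0, 90); y1 <- runif(200, 0, 90)
    det <- stand_detections(tibble::tibble(
      x1 = x1, y1 = y1, x2 = x1 + runif(200, 5, 20), y2 = y1 + runif(200, 5, 20),
      cx = x1 + 5, cy = y1 + 5, score = runif(200)))
    for (thr in c(0.1, 0.3, 0.6)) {
      kept <- non_max_suppression(det, thr)
      oracle_idx <- nms_oracle(det, thr)
      expect_setequal(paste(kept$x1, kept$y1, kept$score),
                      paste(det$x1[oracle_idx], det$y1[oracle_idx],
                            det$score[oracle_idx]))
    }
  })
})

test_that("detect_stands localizes well-separated plants and keeps the raw count", {
  a <- point_annotations(c(10, 30, 10), c(10, 12, 32))
  m <- render_density_map(a, 45, 45, sigma_policy(fallback_sigma = 2, k = 9))
  res <- detect_stands(m, threshold = 1e-4, min_distance = 8, box_size = 10,
                       iou_threshold = 0.3)
  expect_equal(nrow(res$detections), 3)
  expect_equal(res$count, 3, tolerance = 1e-6)
  ord <- order(res$detections$cx, res$detections$cy)
  expect_true(all(abs(sort(res$detections$cx) - sort(a$x)) <= 1))

  zero <- detect_stands(density_map(matrix(0, 20, 20)))
  expect_equal(zero$count, 0)
  expect_equal(nrow(zero$detections), 0)

  # the count never depends on post-processing parameters
  expect_equal(detect_stands(m, threshold = 0.05, min_distance = 20,
                             box_size = 5, iou_threshold = 0.9)$count,
               count_from_density(m))
})

test_that("detections export to TSV and LabelMe rectangles", {
  det <- stand_detections(tibble::tibble(
    x1 = 0, y1 = 0, x2 = 10, y2 = 10, cx = 5, cy = 5, score = 0.7))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_detections(det, tsv, image_id = "img1")
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$image_id, "img1")
  expect_equal(back$x2, 10)

  js <- withr::local_tempfile(fileext = ".json")
  write_detections(det, js, image_id = "img1", image_h = 20, image_w = 20)
  doc <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(doc$shapes[[1]]$shape_type, "rectangle")
})
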