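# Shared fixtures: all test data is built in code at run time.

# A deterministic little field image with plants on a plain background.
make_patch_fixture <- function(size = 48, counts = 3, seed = 1) {
  cfg <- synthetic_field_config(image_size = c(size, size),
                                count_range = c(counts, counts),
                                stage = "V2", seed = seed)
  sim <- generate_field_image(cfg, seed = seed)
  sim
}

# Build training patches directly from synthetic images (no augmentation),
# used by the training tests.
make_training_patches <- function(n, size = 48, count_range = c(1, 5),
                                  stage = "V2", seed = 1,
                                  policy = sigma_policy()) {
  cfg <- synthetic_field_config(image_size = c(size, size),
                                count_range = count_range, stage = stage,
                                seed = seed)
  lapply(seq_len(n), function(i) {
    sim <- generate_field_image(cfg, seed = seed + 1000L * i)
    level <- list(image = sim$image, annotations = sim$annotations, scale = 1)
    random_crop(level, patch_size = size, policy = policy,
                seed = seed + i, offset = c(0, 0))
  })
}

# Exhaustive O(n^2) oracle for the mean k-NN distance.
knn_oracle <- function(points, index, k) {
  d <- sqrt((points$x - points$x[index])^2 + (points$y - points$y[index])^2)
  mean(sort(d[-index])[seq_len(k)])
}

# Independent greedy NMS oracle working from plain loops.
nms_oracle <- function(boxes, thr) {
  iou <- function(a, b) {
    iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- iw * ih
    u <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
    if (u <= 0) 0 else inter / u
  }
  ord <- order(-boxes$score, boxes$cy, boxes$cx)
  kept <- list()
  kept_idx <- integer(0)
  for (i in ord) {
    bi <- c(boxes$x1[i], boxes$y1[i], boxes$x2[i], boxes$y2[i])
    ok <- TRUE
    for (b in kept) if (iou(bi, b) > thr) { ok <- FALSE; break }
    if (ok) { kept[[length(kept) + 1]] <- bi; kept_idx <- c(kept_idx, i) }
  }
  sort(kept_idx)
}

# Random count records for metric fuzz tests.
random_records <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    c_pred = runif(n, 0, 30),
    c_gt = sample(1:30, n, replace = TRUE)))
}
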