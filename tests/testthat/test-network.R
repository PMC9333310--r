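test_that("the backbone follows the VGG filter plan and width scaling", {
  full <- build_network(network_config(width_multiplier = 1), seed = 1)
  expect_equal(dim(full$layers$conv1_1$W), c(3, 3, 3, 64))
  expect_equal(dim(full$layers$conv4_3$W)[4], 512)

  quarter <- build_network(network_config(width_multiplier = 0.25), seed = 1)
  expect_equal(dim(quarter$layers$conv1_1$W)[4], 16)
  expect_equal(dim(quarter$layers$deconv1$W)[4], 32)

  # same seed: bit-identical parameters
  again <- build_network(network_config(width_multiplier = 0.25), seed = 1)
  expect_identical(quarter$layers, again$layers)
  other <- build_network(network_config(width_multiplier = 0.25), seed = 2)
  expect_false(identical(quarter$layers$conv1_1$W, other$layers$conv1_1$W))

  expect_error(network_config(input_size = 4), "input_size")
  expect_error(network_config(width_multiplier = 0), "width_multiplier")
})

test_that("backbone output is exactly 1/8 for inputs divisible by 8", {
  cfg <- network_config()
  for (s in c(8, 16, 64, 304, 800)) {
    expect_equal(output_spatial_shape(cfg, s, s)$backbone, c(s / 8, s / 8))
  }
  # non-multiples floor-halve three times
  expect_equal(output_spatial_shape(cfg, 300, 300)$backbone, c(37, 37))
  expect_error(output_spatial_shape(cfg, 4, 300), "8")
})

test_that("the deconvolution head restores sizes congruent to 4 mod 8", {
  cfg <- network_config()
  for (s in c(12, 20, 300, 308, 1028)) {
    expect_equal(output_spatial_shape(cfg, s, s)$final, c(s, s))
  }
  # rectangular case
  sh <- output_spatial_shape(cfg, 772, 1028)
  expect_equal(sh$final, c(772, 1028))
})

test_that("forward passes produce non-negative maps of the input size", {
  net <- build_network(network_config(width_multiplier = 0.05), seed = 3)
  withr::with_seed(8, {
    for (s in list(c(20, 20), c(24, 36), c(17, 31))) {
      x <- array(runif(prod(s) * 3, 0, 255), c(s, 3))
      m <- forward_density(net, x)
      expect_equal(dim(m), s)
      expect_gte(min(m), 0)
    }
  })
  # zero image through zero biases stays zero end to end
  z <- forward_density(net, array(0, c(32, 32, 3)))
  expect_equal(max(abs(z)), 0)
  expect_error(forward_density(net, array(0, c(4, 20, 3))), "8 px")
})

test_that("analytic gradients agree with finite differences", {
  net <- build_network(network_config(width_multiplier = 0.05), seed = 3)
  # nonzero biases keep pre-activations off the ReLU kink, where the
  # subgradient and the finite difference legitimately disagree
  withr::with_seed(4, {
    for (nm in names(net$layers)) {
      if (!is.null(net$layers[[nm]]$b)) {
        net$layers[[nm]]$b <- rnorm(length(net$layers[[nm]]$b), 0, 0.05)
      }
    }
    x <- array(rnorm(20 * 20 * 3), c(20, 20, 3))
    gt <- matrix(abs(rnorm(400, 0, 0.05)), 20, 20)
    loss_of <- function(n) sum((standcount:::net_forward(n, x)$out - gt)^2)
    fw <- standcount:::net_forward(net, x, keep = TRUE)
    grads <- standcount:::net_backward(net, fw$caches, 2 * (fw$out - gt))
    eps <- 1e-5
    for (nm in c("conv1_1", "conv3_2", "conv4_3", "branch16", "branch32",
                 "fuse", "deconv1", "deconv2", "deconv3", "head")) {
      for (slot in c("W", "b")) {
        arr <- net$layers[[nm]][[slot]]
        for (i in sample(length(arr), min(3, length(arr)))) {
          n2 <- net
          n2$layers[[nm]][[slot]][i] <- arr[i] + eps
          lp <- loss_of(n2)
          n2$layers[[nm]][[slot]][i] <- arr[i] - eps
          lm <- loss_of(n2)
          num <- (lp - lm) / (2 * eps)
          ana <- grads[[nm]][[if (slot == "W") "dW" else "db"]][i]
          expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
        }
      }
    }
  })
})

test_that("the Euclidean loss is the mean squared map distance", {
  a <- matrix(1, 2, 2); b <- matrix(0, 2, 2)
  expect_equal(euclidean_loss(a, a), 0)
  expect_equal(euclidean_loss(a, b), 4)
  expect_equal(euclidean_loss(list(a, b), list(b, b)), 2)
  expect_error(euclidean_loss(list(a), list(a, b)), "Length")
  expect_error(euclidean_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "pair 1")
})

test_that("the architecture summary enumerates parameterized layers", {
  net <- build_network(network_config(width_multiplier = 0.1), seed = 1)
  tab <- network_summary(net)
  expect_equal(nrow(tab), 20)  # 13 backbone + 2 branches + fuse + 3 deconv + head
  expect_equal(sum(tab$type == "pool"), 3)
  expect_true(all(tab$parameters[tab$type != "pool"] > 0))
})
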