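#' Network architecture configuration
#'
#' The counting network is fully convolutional: a truncated VGG-16 backbone
#' (the ten 3x3 convolution layers up to and including the conv4 block,
#' with three 2x2 max-poolings, so the feature map is 1/8 of the input
#' resolution), two extra stride-2 convolution branches producing 1/16 and
#' 1/32 maps, zero-padded channel concatenation of the three scales, a 3x3
#' fusion convolution, three stride-2 transposed convolutions that restore
#' the input resolution (the first with 'valid' padding, the rest 'same'),
#' and a final 1x1 convolution with a ReLU so the predicted density is
#' non-negative.
#'
#' `width_multiplier` scales every filter count (to a minimum of 1) so that
#' desk-scale tests can exercise the full topology cheaply; shapes do not
#' depend on it.
#'
#' @param input_size nominal training patch side, pixels (inference accepts
#'   any size `>= 8`; see [forward_density()]).
#' @param width_multiplier filter-count scale factor in (0, 1].
#' @param fusion_filters filters in the fusion convolution (before width
#'   scaling).
#' @param backbone_filters filters of the ten backbone convolutions.
#' @param branch_filters filters of the two stride-2 scale branches
#'   (1/16 and 1/32).
#' @param deconv_filters filters of the three transposed convolutions.
#' @param nonneg_output apply the final ReLU (densities are non-negative).
#' @param norm_mean,norm_sd input standardization constants applied after
#'   scaling pixels to `[0, 1]`.
#' @return a `network_config` list.
#' @export
network_config <- function(input_size = 300L,
                           width_multiplier = 1,
                           fusion_filters = 128L,
                           backbone_filters = c(64, 64, 128, 128, 256, 256, 256, 512, 512, 512),
                           branch_filters = c(256, 128),
                           deconv_filters = c(128, 64, 32),
                           nonneg_output = TRUE,
                           norm_mean = 0,
                           norm_sd = 1) {
  if (input_size < 8) abort("`input_size` must be >= 8.")
  if (width_multiplier <= 0 || width_multiplier > 1) {
    abort("`width_multiplier` must be in (0, 1].")
  }
  if (length(backbone_filters) != 10) abort("`backbone_filters` must list the 10 VGG conv layers.")
  if (length(deconv_filters) != 3) abort("exactly three stride-2 deconvolution layers are used.")
  scale_f <- function(f) pmax(1L, as.integer(round(f * width_multiplier)))
  structure(list(
    input_size = as.integer(input_size),
    width_multiplier = width_multiplier,
    backbone_filters = scale_f(backbone_filters),
    branch_filters = scale_f(branch_filters),
    fusion_filters = scale_f(fusion_filters),
    deconv_filters = scale_f(deconv_filters),
    nonneg_output = isTRUE(nonneg_output),
    norm_mean = norm_mean, norm_sd = norm_sd),
    class = "network_config")
}

# Backbone layout: conv name or "pool", paired with filter counts in order.
backbone_plan <- function(config) {
  f <- config$backbone_filters
  list(
    list(name = "conv1_1", filters = f[1]), list(name = "conv1_2", filters = f[2]),
    list(name = "pool1"),
    list(name = "conv2_1", filters = f[3]), list(name = "conv2_2", filters = f[4]),
    list(name = "pool2"),
    list(name = "conv3_1", filters = f[5]), list(name = "conv3_2", filters = f[6]),
    list(name = "conv3_3", filters = f[7]),
    list(name = "pool3"),
    list(name = "conv4_1", filters = f[8]), list(name = "conv4_2", filters = f[9]),
    list(name = "conv4_3", filters = f[10]))
}

#' Spatial shapes through the network
#'
#' Pure shape arithmetic, no parameters needed. The backbone applies three
#' floor-halving 2x2 max-pools (exactly 1/8 for inputs that are multiples
#' of 8); the head applies one 'valid' stride-2 kernel-3 transposed
#' convolution (`out = (in - 1) * 2 + 3`) followed by two 'same' stride-2
#' ones (`out = 2 * in`). For inputs congruent to 4 (mod 8) — e.g. 300 —
#' the final output equals the input size exactly.
#'
#' @param config a [network_config()] (shapes do not depend on it, but the
#'   signature keeps the architecture explicit).
#' @param input_h,input_w input dimensions, both `>= 8`.
#' @return a list with per-stage `(h, w)` pairs: `backbone` (1/8 map),
#'   `scale16`, `scale32`, and `final`.
#' @export
output_spatial_shape <- function(config, input_h, input_w) {
  if (input_h < 8 || input_w < 8) abort("Inputs smaller than 8 px are not supported.")
  halve3 <- function(s) { for (i in 1:3) s <- s %/% 2L; s }
  hb <- halve3(as.integer(input_h)); wb <- halve3(as.integer(input_w))
  s2 <- function(s) (s + 1L) %/% 2L        # stride-2 'same' conv: ceil(s/2)
  h16 <- s2(hb); w16 <- s2(wb)
  h32 <- s2(h16); w32 <- s2(w16)
  hd <- (hb - 1L) * 2L + 3L; wd <- (wb - 1L) * 2L + 3L  # 'valid' deconv
  hf <- hd * 4L; wf <- wd * 4L                          # two 'same' deconvs
  list(backbone = c(hb, wb), scale16 = c(h16, w16), scale32 = c(h32, w32),
       final = c(hf, wf))
}

#' Initialize network parameters (Xavier/Glorot uniform)
#'
#' Weights are drawn from `U(-a, a)` with `a = sqrt(6 / (fan_in + fan_out))`
#' (fans include the kernel area); biases start at zero. Deterministic for
#' a fixed seed.
#'
#' @param config a [network_config()].
#' @param seed integer seed.
#' @return a `stand_network` object: the configuration plus per-layer
#'   weight/bias arrays and an iteration counter.
#' @export
initialize_parameters <- function(config, seed = 1L) {
  withr::with_seed(seed, {
    xavier <- function(k, cin, cout) {
      fan_in <- k * k * cin; fan_out <- k * k * cout
      a <- sqrt(6 / (fan_in + fan_out))
      array(runif(k * k * cin * cout, -a, a), c(k, k, cin, cout))
    }
    conv_layer <- function(name, k, cin, cout, stride = 1L, pad = "same",
                           activation = "relu", type = "conv") {
      list(name = name, type = type, k = k, cin = cin, cout = cout,
           stride = stride, pad = pad, activation = activation,
           W = xavier(k, cin, cout), b = numeric(cout))
    }
    layers <- list()
    cin <- 3L
    for (spec in backbone_plan(config)) {
      if (startsWith(spec$name, "pool")) {
        layers[[spec$name]] <- list(name = spec$name, type = "pool", size = 2L)
      } else {
        layers[[spec$name]] <- conv_layer(spec$name, 3L, cin, spec$filters)
        cin <- spec$filters
      }
    }
    c512 <- cin
    layers$branch16 <- conv_layer("branch16", 3L, c512, config$branch_filters[1], stride = 2L)
    layers$branch32 <- conv_layer("branch32", 3L, config$branch_filters[1],
                                  config$branch_filters[2], stride = 2L)
    cat_ch <- c512 + sum(config$branch_filters)
    layers$fuse <- conv_layer("fuse", 3L, cat_ch, config$fusion_filters)
    layers$deconv1 <- conv_layer("deconv1", 3L, config$fusion_filters,
                                 config$deconv_filters[1], stride = 2L,
                                 pad = "valid", type = "deconv")
    layers$deconv2 <- conv_layer("deconv2", 3L, config$deconv_filters[1],
                                 config$deconv_filters[2], stride = 2L,
                                 pad = "same", type = "deconv")
    layers$deconv3 <- conv_layer("deconv3", 3L, config$deconv_filters[2],
                                 config$deconv_filters[3], stride = 2L,
                                 pad = "same", type = "deconv")
    layers$head <- conv_layer("head", 1L, config$deconv_filters[3], 1L,
                              activation = if (config$nonneg_output) "relu" else "linear")
    structure(list(config = config, layers = layers, iteration = 0L),
              class = "stand_network")
  })
}

#' @rdname initialize_parameters
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  initialize_parameters(config, seed)
}

#' @export
print.stand_network <- function(x, ...) {
  np <- sum(purrr::map_dbl(x$layers, function(l) length(l$W) + length(l$b)))
  cat(sprintf("<stand_network> width x%.2f, %s parameters, iteration %d\n",
              x$config$width_multiplier, format(np, big.mark = ","), x$iteration))
  invisible(x)
}

#' Architecture summary table
#'
#' @param network a `stand_network`.
#' @param input_h,input_w input size used to report output shapes.
#' @return a tibble: layer, type, kernel, stride, filters, parameters.
#' @export
network_summary <- function(network, input_h = network$config$input_size,
                            input_w = input_h) {
  rows <- purrr::map(network$layers, function(l) {
    tibble(layer = l$name, type = l$type,
           kernel = if (l$type == "pool") l$size else l$k,
           stride = if (l$type == "pool") l$size else l$stride,
           filters = if (l$type == "pool") NA_integer_ else l$cout,
           parameters = if (l$type == "pool") 0L else length(l$W) + length(l$b))
  })
  dplyr::bind_rows(rows)
}

#' Mean pixel-wise squared-L2 loss between density maps
#'
#' The training objective: the mean over images of the squared Euclidean
#' norm of the difference between predicted and ground-truth density maps.
#' Zero iff every pair is identical.
#'
#' @param predicted,truth lists of density maps (or single maps), pairwise
#'   shape-matched.
#' @return a non-negative scalar.
#' @export
euclidean_loss <- function(predicted, truth) {
  if (is.matrix(predicted)) predicted <- list(predicted)
  if (is.matrix(truth)) truth <- list(truth)
  if (length(predicted) != length(truth)) {
    abort(sprintf("Length mismatch: %d predicted vs %d truth maps.",
                  length(predicted), length(truth)))
  }
  sq <- vapply(seq_along(predicted), function(i) {
    p <- predicted[[i]]; t <- truth[[i]]
    if (!all(dim(p) == dim(t))) {
      abort(sprintf("Shape mismatch in pair %d: %s vs %s.", i,
                    paste(dim(p), collapse = "x"), paste(dim(t), collapse = "x")))
    }
    sum((p - t)^2)
  }, numeric(1))
  mean(sq)
}
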