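# Forward and backward passes. Activations are H x W x C arrays; layer
# parameters live in net$layers (see initialize_parameters). All padding
# arithmetic follows the TensorFlow convention: 'same' stride-s convolution
# pads a total of max((ceil(in/s) - 1) * s + k - in, 0), excess on the
# bottom/right; the transposed convolutions invert that, which is what makes
# a 300 px patch come back out at exactly 300 px
# (300 -> 150 -> 75 -> 37 -> 75 -> 150 -> 300).

same_pads <- function(inp, k, stride) {
  total <- max((ceiling(inp / stride) - 1L) * stride + k - inp, 0L)
  beg <- total %/% 2L
  c(beg, total - beg)
}

conv_pads <- function(l, h, w) {
  if (l$pad == "valid") return(c(0L, 0L, 0L, 0L))
  c(same_pads(h, l$k, l$stride), same_pads(w, l$k, l$stride))
}

wmat <- function(l) matrix(l$W, ncol = dim(l$W)[4])

flip_kernel <- function(W) {
  k <- dim(W)[1]
  W[k:1, k:1, , , drop = FALSE]
}

# ReLU commutes with spatial cropping, so deconv layers apply it inside the
# fused conv kernel before the 'same'-padding crop.
layer_forward <- function(l, x, keep = FALSE) {
  if (l$type == "pool") {
    r <- cpp_maxpool_fw(x, l$size)
    return(list(out = r$out, cache = list(argmax = r$argmax, dim_in = dim(x))))
  }
  is_relu <- identical(l$activation, "relu")
  if (l$type == "conv") {
    p <- conv_pads(l, dim(x)[1], dim(x)[2])
    r <- cpp_conv_fw(x, wmat(l), l$b, l$k, l$stride, p[1], p[2], p[3], p[4],
                     is_relu, keep)
    z <- r$out
    cache <- if (keep) list(x = x, pads = p, cols = r$cols) else NULL
  } else {  # deconv: conv of the zero-stuffed input with the flipped kernel
    xs <- cpp_zero_stuff(x, l$stride)
    r <- cpp_conv_fw(xs, matrix(flip_kernel(l$W), ncol = dim(l$W)[4]), l$b,
                     l$k, 1L, l$k - 1L, l$k - 1L, l$k - 1L, l$k - 1L,
                     is_relu, keep)
    z <- r$out
    crop <- 0L
    if (l$pad == "same") {
      # full output (in-1)*s + k exceeds in*s by k - s; crop the excess at
      # the bottom/right (mirror of 'same' forward padding with beg = 0)
      crop <- l$k - l$stride
      z <- z[seq_len(dim(z)[1] - crop), seq_len(dim(z)[2] - crop), , drop = FALSE]
    }
    cache <- if (keep) list(x = x, xs_dim = dim(xs), crop = crop, cols = r$cols) else NULL
  }
  if (!is.finite(sum(z))) {
    abort(sprintf("Non-finite activations in layer '%s'.", l$name))
  }
  if (keep && is_relu) cache$out <- z
  list(out = z, cache = cache)
}

layer_backward <- function(l, cache, dout, need_dx = TRUE) {
  if (l$type == "pool") {
    d <- cache$dim_in
    return(list(dx = cpp_maxpool_bw(cache$argmax, dout, d[1], d[2], d[3])))
  }
  if (!is.null(cache$out)) dout <- cpp_relu_gate(dout, cache$out)
  if (l$type == "conv") {
    p <- cache$pads
    g <- cpp_conv_bw(cache$x, wmat(l), dout, cache$cols %||% matrix(0, 0, 0),
                     l$k, l$stride, p[1], p[2], p[3], p[4], need_dx)
    return(list(dx = g$dx, dW = array(g$dW, dim(l$W)), db = as.numeric(g$db)))
  }
  # deconv: pad the cropped region of dout back with zeros, then run the
  # equivalent-convolution backward and subsample the stuffed gradient
  if (cache$crop > 0) {
    full <- array(0, c(dim(dout)[1] + cache$crop, dim(dout)[2] + cache$crop, dim(dout)[3]))
    full[seq_len(dim(dout)[1]), seq_len(dim(dout)[2]), ] <- dout
    dout <- full
  }
  xs <- cpp_zero_stuff(cache$x, l$stride)
  g <- cpp_conv_bw(xs, matrix(flip_kernel(l$W), ncol = dim(l$W)[4]), dout,
                   cache$cols %||% matrix(0, 0, 0),
                   l$k, 1L, l$k - 1L, l$k - 1L, l$k - 1L, l$k - 1L, need_dx)
  dWf <- array(g$dW, dim(l$W))
  out <- list(dW = flip_kernel(dWf), db = as.numeric(g$db))
  if (need_dx) out$dx <- cpp_subsample(g$dx, l$stride)
  out
}

# Zero-pad a smaller feature map to (h, w), centered (excess bottom/right).
pad_to <- function(x, h, w) {
  d <- dim(x)
  if (d[1] == h && d[2] == w) return(list(out = x, off = c(0L, 0L)))
  ot <- (h - d[1]) %/% 2L
  ol <- (w - d[2]) %/% 2L
  out <- array(0, c(h, w, d[3]))
  out[ot + seq_len(d[1]), ol + seq_len(d[2]), ] <- x
  list(out = out, off = c(ot, ol))
}

net_forward <- function(net, x, keep = FALSE) {
  L <- net$layers
  caches <- list()
  bb_names <- names(L)[seq_len(13)]  # through conv4_3
  a <- x
  for (nm in bb_names) {
    r <- layer_forward(L[[nm]], a, keep)
    if (keep) caches[[nm]] <- r$cache
    a <- r$out
  }
  bb <- a
  r16 <- layer_forward(L$branch16, bb, keep); if (keep) caches$branch16 <- r16$cache
  r32 <- layer_forward(L$branch32, r16$out, keep); if (keep) caches$branch32 <- r32$cache
  h <- dim(bb)[1]; w <- dim(bb)[2]
  p16 <- pad_to(r16$out, h, w)
  p32 <- pad_to(r32$out, h, w)
  cat_in <- array(c(bb, p16$out, p32$out),
                  c(h, w, dim(bb)[3] + dim(p16$out)[3] + dim(p32$out)[3]))
  if (keep) {
    caches$concat <- list(ch = c(dim(bb)[3], dim(p16$out)[3], dim(p32$out)[3]),
                          off16 = p16$off, dim16 = dim(r16$out),
                          off32 = p32$off, dim32 = dim(r32$out))
  }
  a <- cat_in
  for (nm in c("fuse", "deconv1", "deconv2", "deconv3", "head")) {
    r <- layer_forward(L[[nm]], a, keep)
    if (keep) caches[[nm]] <- r$cache
    a <- r$out
  }
  list(out = a[, , 1], caches = caches)
}

net_backward <- function(net, caches, dmap) {
  L <- net$layers
  grads <- list()
  dout <- array(dmap, c(dim(dmap), 1L))
  for (nm in rev(c("fuse", "deconv1", "deconv2", "deconv3", "head"))) {
    g <- layer_backward(L[[nm]], caches[[nm]], dout)
    if (!is.null(g$dW)) grads[[nm]] <- list(dW = g$dW, db = g$db)
    dout <- g$dx
  }
  cc <- caches$concat
  ch <- cc$ch
  d_bb_cat <- dout[, , seq_len(ch[1]), drop = FALSE]
  d16p <- dout[, , ch[1] + seq_len(ch[2]), drop = FALSE]
  d32p <- dout[, , ch[1] + ch[2] + seq_len(ch[3]), drop = FALSE]
  d16 <- d16p[cc$off16[1] + seq_len(cc$dim16[1]),
              cc$off16[2] + seq_len(cc$dim16[2]), , drop = FALSE]
  d32 <- d32p[cc$off32[1] + seq_len(cc$dim32[1]),
              cc$off32[2] + seq_len(cc$dim32[2]), , drop = FALSE]
  g32 <- layer_backward(L$branch32, caches$branch32, d32)
  grads$branch32 <- list(dW = g32$dW, db = g32$db)
  g16 <- layer_backward(L$branch16, caches$branch16, d16 + g32$dx)
  grads$branch16 <- list(dW = g16$dW, db = g16$db)
  dout <- d_bb_cat + g16$dx
  bb_names <- rev(names(L)[seq_len(13)])
  for (nm in bb_names) {
    g <- layer_backward(L[[nm]], caches[[nm]], dout,
                        need_dx = nm != "conv1_1")
    if (!is.null(g$dW)) grads[[nm]] <- list(dW = g$dW, db = g$db)
    dout <- g$dx
  }
  grads
}

normalize_input <- function(pixels, config) {
  (pixels / 255 - config$norm_mean) / config$norm_sd
}

# Smallest size >= s congruent to 4 (mod 8); sizes of that form are exactly
# restored by the deconvolution head (8m + 4 -> 4m + 2 -> 2m + 1 -> m ->
# 2m + 1 -> 4m + 2 -> 8m + 4).
pad_target <- function(s) {
  r <- (4L - s %% 8L) %% 8L
  as.integer(s + r)
}

reflect_pad_br <- function(px, th, tw) {
  h <- dim(px)[1]; w <- dim(px)[2]
  ri <- c(seq_len(h), if (th > h) h - seq_len(th - h))
  ci <- c(seq_len(w), if (tw > w) w - seq_len(tw - w))
  px[ri, ci, , drop = FALSE]
}

#' Predict a density map for an image
#'
#' Runs the network forward. Arbitrary input sizes (`>= 8` per axis) are
#' handled by reflect-padding the image bottom/right up to the next size
#' congruent to 4 (mod 8) — the sizes the deconvolution head restores
#' exactly — and cropping the output back, so the returned map always has
#' the input's height and width. The predicted stand count is
#' `count_from_density()` of the result.
#'
#' @param network a `stand_network`.
#' @param image a `field_image`, a `training_patch`, or an `H x W x 3`
#'   pixel array on the 0--255 scale.
#' @return a `density_map` of the same height/width as the input.
#' @export
forward_density <- function(network, image) {
  px <- if (inherits(image, "field_image")) image$pixels
        else if (inherits(image, "training_patch")) image$pixels
        else image
  h <- dim(px)[1]; w <- dim(px)[2]
  if (h < 8 || w < 8) abort("Inputs smaller than 8 px per axis are not supported.")
  th <- pad_target(h); tw <- pad_target(w)
  if (th != h || tw != w) px <- reflect_pad_br(px, th, tw)
  x <- normalize_input(px, network$config)
  out <- net_forward(network, x, keep = FALSE)$out
  map <- out[seq_len(h), seq_len(w), drop = FALSE]
  if (network$config$nonneg_output) map[map < 0] <- 0
  density_map(map)
}
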