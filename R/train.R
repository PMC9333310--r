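#' Training configuration
#'
#' Defaults follow the full-scale recipe: Adam with initial learning rate
#' 3e-4 decayed to 25e-6, mini-batches of 24 patches, 80,000 iterations,
#' Xavier initialization. The decay shape is configurable (the published
#' recipe says only "gradually decayed"); the default cosine schedule is
#' smooth and hits both endpoints exactly.
#'
#' @param lr_initial,lr_final learning-rate endpoints (`0 < lr_final <=
#'   lr_initial`).
#' @param batch_size patches per iteration.
#' @param total_iterations optimizer steps.
#' @param schedule decay shape: `"cosine"`, `"linear"` or `"step"` (a
#'   10-step geometric staircase).
#' @param seed integer seed controlling initialization and data order.
#' @param checkpoint_every write a checkpoint every this many iterations
#'   (`Inf` disables).
#' @param log_every record the loss every this many iterations (the first
#'   and last iteration are always recorded).
#' @param clip_grad_norm optional global gradient-norm ceiling (`NULL`
#'   disables clipping).
#' @return a `train_config` list.
#' @export
train_config <- function(lr_initial = 3e-4, lr_final = 25e-6,
                         batch_size = 24L, total_iterations = 80000L,
                         schedule = c("cosine", "linear", "step"),
                         seed = 1L, checkpoint_every = Inf,
                         log_every = 10L, clip_grad_norm = NULL) {
  schedule <- match.arg(schedule)
  if (lr_final <= 0 || lr_final > lr_initial) abort("Need 0 < lr_final <= lr_initial.")
  if (batch_size < 1) abort("`batch_size` must be >= 1.")
  if (total_iterations < 1) abort("`total_iterations` must be >= 1.")
  structure(list(lr_initial = lr_initial, lr_final = lr_final,
                 batch_size = as.integer(batch_size),
                 total_iterations = as.integer(total_iterations),
                 schedule = schedule, seed = as.integer(seed),
                 checkpoint_every = checkpoint_every,
                 log_every = as.integer(log_every),
                 clip_grad_norm = clip_grad_norm),
            class = "train_config")
}

#' Learning rate at a given iteration
#'
#' Monotone non-increasing; returns exactly `lr_initial` at iteration 0 and
#' exactly `lr_final` at `total_iterations`.
#'
#' @param iteration step in `[0, total_iterations]`.
#' @param config a [train_config()].
#' @return the learning rate.
#' @export
learning_rate_at <- function(iteration, config = train_config()) {
  t <- iteration; T <- config$total_iterations
  if (any(t < 0) || any(t > T)) {
    abort(sprintf("`iteration` must be in [0, %d].", T))
  }
  lr0 <- config$lr_initial; lrf <- config$lr_final
  switch(config$schedule,
    cosine = lrf + 0.5 * (lr0 - lrf) * (1 + cos(pi * t / T)),
    linear = lr0 + (lrf - lr0) * t / T,
    step   = lr0 * (lrf / lr0)^(floor(10 * t / T) / 10))
}

# One Adam update on a named list-of-arrays parameter/gradient structure.
adam_step <- function(layers, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (slot in c("W", "b")) {
      g <- grads[[nm]][[if (slot == "W") "dW" else "db"]]
      key <- paste0(nm, ".", slot)
      m <- state$m[[key]]; v <- state$v[[key]]
      if (is.null(m)) { m <- g * 0; v <- g * 0 }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      state$m[[key]] <- m; state$v[[key]] <- v
      layers[[nm]][[slot]] <- layers[[nm]][[slot]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(layers = layers, state = state)
}

#' Train the counting network
#'
#' Runs `total_iterations` Adam steps on shuffled mini-batches of training
#' patches, minimizing the mean pixel-wise squared-L2 loss between predicted
#' and ground-truth density maps. Fully reproducible for a fixed
#' `config$seed` (initialization and data order included). If `batch_size`
#' exceeds the number of patches, batches are sampled with replacement (with
#' a warning).
#'
#' @param patches a non-empty list of `training_patch` objects with equal
#'   pixel dimensions.
#' @param net_config a [network_config()].
#' @param config a [train_config()].
#' @param network optionally, an existing `stand_network` to continue
#'   training (its config overrides `net_config`).
#' @param checkpoint_dir directory for checkpoints (only used when
#'   `config$checkpoint_every` is finite).
#' @return a `stand_fit`: `list(network, history, config)` where `history`
#'   is a tibble with columns `iteration`, `lr`, `loss`.
#' @export
train_network <- function(patches, net_config = network_config(),
                          config = train_config(), network = NULL,
                          checkpoint_dir = NULL) {
  if (length(patches) == 0) abort("`patches` must be non-empty.")
  if (is.null(network)) network <- initialize_parameters(net_config, config$seed)
  n <- length(patches)
  with_replacement <- config$batch_size > n
  if (with_replacement) {
    warn(sprintf("batch_size (%d) exceeds the number of patches (%d): sampling with replacement.",
                 config$batch_size, n))
  }
  # Pre-normalize inputs once; patches share the network's padding-free
  # training path (their size is expected to be restored exactly, i.e.
  # congruent to 4 mod 8 after padding; others are reflect-padded here).
  xs <- purrr::map(patches, function(p) {
    px <- p$pixels
    th <- pad_target(dim(px)[1]); tw <- pad_target(dim(px)[2])
    if (th != dim(px)[1] || tw != dim(px)[2]) px <- reflect_pad_br(px, th, tw)
    normalize_input(px, network$config)
  })
  gts <- purrr::map(patches, function(p) unclass(p$density))
  hdim <- dim(xs[[1]])
  if (!all(purrr::map_lgl(xs, function(x) all(dim(x) == hdim)))) {
    abort("All training patches must share the same pixel dimensions.")
  }
  history <- vector("list", config$total_iterations)
  withr::with_seed(config$seed + 1L, {
    adam <- list(t = 0L, m = list(), v = list())
    queue <- integer(0)
    for (it in seq_len(config$total_iterations)) {
      if (with_replacement) {
        batch <- sample.int(n, config$batch_size, replace = TRUE)
      } else {
        while (length(queue) < config$batch_size) queue <- c(queue, sample.int(n))
        batch <- queue[seq_len(config$batch_size)]
        queue <- queue[-seq_len(config$batch_size)]
      }
      N <- length(batch)
      loss <- 0
      grads_sum <- NULL
      for (j in batch) {
        fw <- net_forward(network, xs[[j]], keep = TRUE)
        gt <- gts[[j]]
        pred <- fw$out[seq_len(nrow(gt)), seq_len(ncol(gt)), drop = FALSE]
        diff <- pred - gt
        loss <- loss + sum(diff^2) / N
        dmap <- array(0, dim(fw$out))
        dmap[seq_len(nrow(gt)), seq_len(ncol(gt))] <- 2 * diff / N
        g <- net_backward(network, fw$caches, dmap)
        grads_sum <- if (is.null(grads_sum)) g else
          purrr::map2(grads_sum, g[names(grads_sum)], function(a, b) {
            list(dW = a$dW + b$dW, db = a$db + b$db)
          })
      }
      if (!is.finite(loss)) {
        abort(sprintf("Non-finite loss at iteration %d.", it))
      }
      if (!is.null(config$clip_grad_norm)) {
        gn <- sqrt(sum(purrr::map_dbl(grads_sum, function(g) sum(g$dW^2) + sum(g$db^2))))
        if (gn > config$clip_grad_norm) {
          sc <- config$clip_grad_norm / gn
          grads_sum <- purrr::map(grads_sum, function(g) list(dW = g$dW * sc, db = g$db * sc))
        }
      }
      lr <- learning_rate_at(it - 1L, config)
      upd <- adam_step(network$layers, grads_sum, adam, lr)
      network$layers <- upd$layers
      adam <- upd$state
      network$iteration <- it
      if (it == 1L || it == config$total_iterations || it %% config$log_every == 0L) {
        history[[it]] <- tibble(iteration = it, lr = lr, loss = loss)
      }
      if (is.finite(config$checkpoint_every) && !is.null(checkpoint_dir) &&
          it %% config$checkpoint_every == 0L) {
        save_checkpoint(network, file.path(checkpoint_dir, sprintf("ckpt_%06d.rds", it)))
      }
    }
  })
  structure(list(network = network,
                 history = dplyr::bind_rows(history),
                 config = config),
            class = "stand_fit")
}

#' @export
print.stand_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<stand_fit> %d iterations; loss %.4g -> %.4g\n",
              x$network$iteration, h$loss[1], h$loss[nrow(h)]))
  invisible(x)
}

#' @rdname train_network
#' @param x a `stand_fit`.
#' @param ... unused.
#' @export
tidy.stand_fit <- function(x, ...) x$history

#' @rdname train_network
#' @export
glance.stand_fit <- function(x, ...) {
  h <- x$history
  tibble(iterations = x$network$iteration,
         initial_loss = h$loss[1],
         final_loss = h$loss[nrow(h)],
         loss_reduction = 1 - h$loss[nrow(h)] / h$loss[1],
         parameters = sum(purrr::map_dbl(x$network$layers,
                                         function(l) length(l$W) + length(l$b))))
}

#' Save / load a network checkpoint
#'
#' Checkpoints carry the configuration, all parameters and the iteration
#' counter.
#'
#' @param network a `stand_network`.
#' @param path checkpoint file path (RDS).
#' @return `path` / the restored `stand_network`.
#' @export
save_checkpoint <- function(network, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) abort(sprintf("Checkpoint not found: '%s'.", path))
  readRDS(path)
}
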