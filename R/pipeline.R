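# Config-driven pipeline dispatch: the same five stages the shell entry
# point exposes (simulate, augment, train, predict, evaluate), callable
# programmatically with a plain named list or a YAML file.

#' Derive a per-module seed from the global seed
#'
#' One global seed fans out deterministically to per-stage seeds via a
#' polynomial string hash of the stage name, so each stage is independently
#' reproducible. Results stay below 2^31.
#'
#' @param seed global integer seed.
#' @param module stage name (character scalar).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, module) {
  h <- 0
  for (code in utf8ToInt(module)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

#' Run one pipeline stage from a configuration
#'
#' `config` is a named list (or path to a YAML file) with a `subcommand`
#' field — one of `simulate`, `augment`, `train`, `predict`, `evaluate` —
#' plus the stage's inputs. A resolved copy of the configuration and a log
#' file are written next to the stage outputs, so every run is reproducible
#' from its resolved config alone.
#'
#' Stage fields (all paths; `seed` and `log_level` are global):
#' * `simulate`: `n_images`, `out_dir`, plus [synthetic_field_config()] fields.
#' * `augment`: `data_dir` (a simulated dataset), `out_dir`, plus
#'   [augmentation_config()] fields.
#' * `train`: `patch_dir`, `out_dir`, plus [network_config()] /
#'   [train_config()] fields under `network` / `training`.
#' * `predict`: `checkpoint`, `data_dir`, `out_dir`, post-processing fields.
#' * `evaluate`: `pred` (TSV with `image_id`, `c_pred`), `truth` (TSV with
#'   `image_id`, `c_gt` and optional `stage`), `out_dir`, `by_stage`.
#'
#' @param config named list or YAML path.
#' @return invisibly, the stage's main artifact (manifest, fit, tibble ...);
#'   errors propagate as conditions (the shell wrapper maps them to a
#'   nonzero exit status).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  sub <- config$subcommand
  if (is.null(sub) || !sub %in% c("simulate", "augment", "train", "predict", "evaluate")) {
    abort("`config$subcommand` must be one of simulate, augment, train, predict, evaluate.")
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                                        sprintf(...)), file = log_path, append = TRUE)
  log_line("stage %s, seed %d", sub, seed)
  result <- switch(sub,
    simulate = {
      cfg <- synthetic_field_config(
        image_size = unlist(config$image_size %||% c(768L, 1024L)),
        count_range = unlist(config$count_range %||% c(5L, 31L)),
        count_distribution = config$count_distribution %||% "uniform",
        stage = config$stage %||% "V3",
        seed = derive_seed(seed, "simulate"))
      generate_field_dataset(cfg, n_images = config$n_images %||% 10L,
                             out_dir = out_dir)
    },
    augment = {
      dataset <- load_field_dataset(config$data_dir)
      acfg <- do.call(augmentation_config, c(
        config$augmentation %||% list(),
        list(seed = derive_seed(seed, "augment"))))
      patches <- build_training_set(dataset, acfg)
      write_patch_set(patches, out_dir)
    },
    train = {
      patches <- read_patch_set(config$patch_dir)
      ncfg <- do.call(network_config, config$network %||% list())
      tcfg <- do.call(train_config, c(config$training %||% list(),
                                      list(seed = derive_seed(seed, "train"))))
      fit <- train_network(patches, ncfg, tcfg, checkpoint_dir = out_dir)
      save_checkpoint(fit$network, file.path(out_dir, "checkpoint.rds"))
      readr::write_tsv(fit$history, file.path(out_dir, "training_log.tsv"))
      fit
    },
    predict = {
      if (!file.exists(config$checkpoint %||% "")) {
        abort(sprintf("Checkpoint not found: '%s'.", config$checkpoint %||% "<missing>"))
      }
      net <- load_checkpoint(config$checkpoint)
      dataset <- load_field_dataset(config$data_dir)
      rows <- purrr::map(dataset, function(item) {
        map <- forward_density(net, item$image)
        det <- detect_stands(map,
                             threshold = config$threshold %||% 1e-3,
                             min_distance = config$min_distance %||% 10,
                             box_size = config$box_size %||% 40,
                             iou_threshold = config$iou_threshold %||% 0.3)
        write_detections(det$detections,
                         file.path(out_dir, paste0(item$image$id, "_detections.tsv")),
                         image_id = item$image$id)
        tibble(image_id = item$image$id, c_pred = det$count,
               n_detections = nrow(det$detections))
      })
      preds <- dplyr::bind_rows(rows)
      readr::write_tsv(preds, file.path(out_dir, "predictions.tsv"))
      preds
    },
    evaluate = {
      pred <- readr::read_tsv(config$pred, show_col_types = FALSE)
      truth <- readr::read_tsv(config$truth, show_col_types = FALSE)
      records <- dplyr::inner_join(pred, truth, by = "image_id")
      res <- if (isTRUE(config$by_stage)) evaluate_by_stage(records)
             else count_metrics(records)
      readr::write_tsv(res, file.path(out_dir, "metrics.tsv"))
      res
    })
  log_line("stage %s done", sub)
  invisible(result)
}

#' Shell-style entry point
#'
#' Thin argument-vector wrapper over [run_pipeline()], used by the
#' `standcount` Rscript shipped under `inst/cli/`. Returns an exit status
#' instead of signalling, so the wrapper can `quit(status = ...)`.
#'
#' @param args character vector, e.g.
#'   `c("simulate", "--n", "20", "--out", "data/", "--seed", "7")`.
#' @return integer exit status (0 on success).
#' @export
stand_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) {
    message("usage: standcount {simulate|augment|train|predict|evaluate} [--config cfg.yaml] [options]")
    return(1L)
  }
  sub <- args[1]
  opts <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--n", type = "integer", default = NULL),
    optparse::make_option("--stage", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--data", type = "character", default = NULL),
    optparse::make_option("--patches", type = "character", default = NULL),
    optparse::make_option("--checkpoint", type = "character", default = NULL),
    optparse::make_option("--pred", type = "character", default = NULL),
    optparse::make_option("--truth", type = "character", default = NULL),
    optparse::make_option("--by-stage", action = "store_true",
                          default = FALSE, dest = "by_stage"),
    optparse::make_option("--seed", type = "integer", default = NULL)))
  parsed <- tryCatch(optparse::parse_args(opts, args = args[-1]),
                     error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(parsed)) return(2L)
  config <- if (!is.null(parsed$config)) yaml::read_yaml(parsed$config) else list()
  config$subcommand <- sub
  # flags win over the YAML file
  flag_map <- list(n = "n_images", stage = "stage", out = "out_dir",
                   data = "data_dir", patches = "patch_dir",
                   checkpoint = "checkpoint", pred = "pred", truth = "truth",
                   by_stage = "by_stage", seed = "seed")
  for (nm in names(flag_map)) {
    if (!is.null(parsed[[nm]]) && !identical(parsed[[nm]], FALSE)) {
      config[[flag_map[[nm]]]] <- parsed[[nm]]
    }
  }
  status <- tryCatch({ run_pipeline(config); 0L },
                     error = function(e) { message("error: ", conditionMessage(e)); 1L })
  status
}
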