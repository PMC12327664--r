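# End-to-end workflows: one YAML-serialisable configuration drives synthesis,
# training, prediction and evaluation; all randomness flows from the single
# root seed, so every artifact is reproducible from (config, seed).

default_run_config <- function() {
  list(
    seed = 1L,
    model = "grid",
    paths = list(dataset = "dataset", checkpoint = "model.rds",
                 metrics = "metrics.json", predictions = "predictions.csv",
                 log = NULL),
    synth = list(width = 1920L, height = 1080L,
                 class_weights = c(0.70, 0.15, 0.14, 0.01),
                 n_regions = 40L, fragmentation = 0.2, noise_sd = 8,
                 n_images = 50L),
    split = list(fraction = 0.8),
    backbone = list(input_width = 448L, input_height = 224L,
                    channel_widths = c(256L, 512L, 1024L, 2048L),
                    units = c(3L, 4L, 6L, 3L),
                    attention_placement = "after_block4",
                    hidden_width = 512L),
    patch = list(patch_size = 880L, resize_stage1 = 224L,
                 resize_stage2 = 448L, threshold = 0.5),
    train = list(epochs = 40L, lr = 1e-3, n_augment = 2L,
                 epochs_stage1 = 30L, epochs_stage2 = 15L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML file (if given) over the package defaults, then applies
#' `overrides` on top. Every stage of the pipeline is driven by one such
#' configuration; its seed is the root of all randomness.
#'
#' @param path Optional YAML file.
#' @param overrides Optional named list merged over the file values.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort_config(paste0("config file not found: ", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_config(cfg, overrides)
  if (!cfg$model %in% c("grid", "patch")) {
    abort_config("model must be 'grid' or 'patch'")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

log_stage <- function(cfg, stage, expr) {
  t0 <- Sys.time()
  res <- force(expr)
  dt <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  line <- paste0("[", stage, "] done in ", dt, " s")
  message(line)
  if (!is.null(cfg$paths$log)) cat(line, "\n", file = cfg$paths$log, append = TRUE)
  res
}

config_backbone <- function(cfg) {
  do.call(backbone_config, cfg$backbone)
}

config_patch_spec <- function(cfg) {
  do.call(patch_spec, cfg$patch)
}

config_split <- function(cfg) {
  data <- load_dataset(cfg$paths$dataset)
  split <- split_by_image(data$image_id, cfg$split$fraction, seed = cfg$seed)
  list(train = data[data$image_id %in% split$train_ids, ],
       test = data[data$image_id %in% split$test_ids, ],
       split = split)
}

#' Run pipeline stages from a configuration
#'
#' `run_synth()` writes a synthetic dataset; `run_train_grid()` /
#' `run_train_patch()` train on the configured train split and write a
#' checkpoint plus a per-epoch loss log CSV; `run_predict()` writes a
#' prediction CSV for every image; `run_eval()` writes a metrics JSON for
#' the held-out test split. Re-running any stage with an identical
#' configuration and seed reproduces its outputs.
#'
#' @param cfg A [read_run_config()] object.
#' @return The stage's main artifact, invisibly.
#' @export
run_synth <- function(cfg) {
  sc <- scene_config(width = cfg$synth$width, height = cfg$synth$height,
                     class_weights = cfg$synth$class_weights,
                     n_regions = cfg$synth$n_regions,
                     fragmentation = cfg$synth$fragmentation,
                     noise_sd = cfg$synth$noise_sd, seed = cfg$seed)
  manifest <- log_stage(cfg, "synth",
                        generate_dataset(sc, cfg$synth$n_images, cfg$paths$dataset))
  invisible(manifest)
}

#' @rdname run_synth
#' @export
run_train_grid <- function(cfg) {
  parts <- config_split(cfg)
  model <- log_stage(cfg, "train-grid",
                     train_grid_model(parts$train, config = config_backbone(cfg),
                                      epochs = cfg$train$epochs, lr = cfg$train$lr,
                                      n_augment = cfg$train$n_augment,
                                      seed = cfg$seed))
  save_checkpoint(model, cfg$paths$checkpoint)
  readr::write_csv(model$loss_trace,
                   paste0(tools::file_path_sans_ext(cfg$paths$checkpoint), "_loss.csv"),
                   progress = FALSE)
  invisible(model)
}

#' @rdname run_synth
#' @export
run_train_patch <- function(cfg) {
  parts <- config_split(cfg)
  model <- log_stage(cfg, "train-patch",
                     train_patch_model(parts$train, spec = config_patch_spec(cfg),
                                       config = config_backbone(cfg),
                                       epochs_stage1 = cfg$train$epochs_stage1,
                                       epochs_stage2 = cfg$train$epochs_stage2,
                                       lr = cfg$train$lr,
                                       n_augment = cfg$train$n_augment,
                                       seed = cfg$seed))
  save_checkpoint(model, cfg$paths$checkpoint)
  readr::write_csv(model$loss_trace,
                   paste0(tools::file_path_sans_ext(cfg$paths$checkpoint), "_loss.csv"),
                   progress = FALSE)
  invisible(model)
}

#' @rdname run_synth
#' @export
run_predict <- function(cfg) {
  model <- load_checkpoint(cfg$paths$checkpoint)
  data <- load_dataset(cfg$paths$dataset)
  rows <- log_stage(cfg, "predict", purrr::map(seq_len(nrow(data)), function(i) {
    img <- source_image(data$image_id[i], read_image(data$path[i]))
    if (inherits(model, "grid_model")) {
      predict_points(img, model)
    } else {
      predict_image_patches(img, model)
    }
  }))
  out <- dplyr::bind_rows(rows)
  readr::write_csv(out, cfg$paths$predictions, progress = FALSE)
  invisible(out)
}

#' @rdname run_synth
#' @export
run_eval <- function(cfg) {
  model <- load_checkpoint(cfg$paths$checkpoint)
  parts <- config_split(cfg)
  report <- log_stage(cfg, "eval", {
    if (inherits(model, "grid_model")) {
      evaluate_grid_model(model, parts$test)$report
    } else {
      evaluate_patch_model(model, parts$test)$metrics
    }
  })
  write_metrics_json(report, cfg$paths$metrics)
  invisible(report)
}

parse_cli_args <- function(args) {
  out <- list(config = NULL, overrides = list())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--config") {
      out$config <- args[i + 1L]; i <- i + 2L
    } else if (a == "--seed") {
      out$overrides$seed <- as.integer(args[i + 1L]); i <- i + 2L
    } else if (a == "--set") {
      kv <- strsplit(args[i + 1L], "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) abort_config(paste0("bad --set expression: ", args[i + 1L]))
      keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
      val <- utils::type.convert(strsplit(kv[2], ",", fixed = TRUE)[[1]], as.is = TRUE)
      node <- val
      for (k in rev(keys)) node <- setNames(list(node), k)
      out$overrides <- merge_config(out$overrides, node)
      i <- i + 2L
    } else {
      abort_config(paste0("unknown argument: ", a))
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `synth`, `train-grid`, `train-patch`,
#' `predict` and `eval`. Flags: `--config <yaml>`, `--seed <int>`, and
#' repeatable `--set key.subkey=value` overrides. A thin executable wrapper
#' is installed at `system.file("cli", "benthoscan.R", package =
#' "benthoscan")`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
benthoscan_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L) abort_config("usage: benthoscan <synth|train-grid|train-patch|predict|eval> [--config file] [--seed n] [--set k=v]")
    cmd <- args[1]
    parsed <- parse_cli_args(args[-1])
    cfg <- read_run_config(parsed$config, parsed$overrides)
    switch(cmd,
           "synth" = run_synth(cfg),
           "train-grid" = run_train_grid(cfg),
           "train-patch" = run_train_patch(cfg),
           "predict" = run_predict(cfg),
           "eval" = run_eval(cfg),
           abort_config(paste0("unknown subcommand: ", cmd)))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
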