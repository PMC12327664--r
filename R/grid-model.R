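# Sparse grid-point classifier. An image is resized to the backbone input,
# the requested pixel coordinates are rescaled through each backbone stage,
# per-block feature vectors are sampled at those cells and concatenated, and
# a fully connected head scores the four habitat classes per point. The
# convolutional trunk (and attention projections) provide a fixed multi-scale
# feature basis; gradient training is applied to the head, which minimises
# the cross-entropy loss averaged across all point labels.

# Geometric + photometric augmentation applied identically to the image and
# its query coordinates: horizontal/vertical flips, small rotation,
# brightness/contrast jitter. Labels ride with the coordinates.
augment_pair <- function(px, coords, max_angle = 10) {
  H <- dim(px)[1]; W <- dim(px)[2]
  x <- coords$x; y <- coords$y
  if (runif(1) < 0.5) {                       # horizontal flip
    px <- px[, W:1, , drop = FALSE]
    x <- W - 1 - x
  }
  if (runif(1) < 0.5) {                       # vertical flip
    px <- px[H:1, , , drop = FALSE]
    y <- H - 1 - y
  }
  angle <- runif(1, -max_angle, max_angle)
  px <- rotate_image(px, angle)
  p <- rotate_points(x, y, W, H, angle)
  x <- clamp(p$x, 0, W - 1); y <- clamp(p$y, 0, H - 1)
  px <- px * runif(1, 0.9, 1.1) + runif(1, -15, 15)   # contrast, brightness
  px <- clamp(px, 0, 255)
  coords$x <- x; coords$y <- y
  list(pixels = px, coords = coords)
}

# Map 0-based pixel coordinates from a W x H image into the backbone input
# frame (pixel-centre alignment, clamped to the input extent).
coords_to_input <- function(x, y, width, height, in_width, in_height) {
  list(x = clamp(floor((x + 0.5) * in_width / width), 0, in_width - 1),
       y = clamp(floor((y + 0.5) * in_height / height), 0, in_height - 1))
}

resolve_scene_rows <- function(data) {
  if (is.character(data) && length(data) == 1L) data <- load_dataset(data)
  if (!is.data.frame(data) || !all(c("image_id", "annotation") %in% names(data))) {
    abort_schema("training data must be a scene tibble (image_id + annotation plus image or path) or a dataset directory")
  }
  if (!("image" %in% names(data)) && !("path" %in% names(data))) {
    abort_schema("scene tibble needs an `image` list-column or a `path` column")
  }
  data
}

row_pixels <- function(row) {
  if ("image" %in% names(row) && !is.null(row$image[[1]])) {
    row$image[[1]]
  } else {
    read_image(row$path)
  }
}

# Featurize one image: resize to the input frame, make `n_augment` jittered
# variants plus the original, forward the trunk once per variant and sample
# the concatenated block features at the (transformed) point coordinates.
featurize_grid_image <- function(px, ann, backbone, n_augment = 0L) {
  cfg <- backbone$config
  H <- dim(px)[1]; W <- dim(px)[2]
  rs <- resize_image(px, cfg$input_width, cfg$input_height)
  cin <- coords_to_input(ann$x, ann$y, W, H, cfg$input_width, cfg$input_height)
  base <- tibble(x = cin$x, y = cin$y, label = ann$label)
  variants <- list(list(pixels = rs, coords = base))
  if (n_augment > 0L) {
    for (a in seq_len(n_augment)) variants[[a + 1L]] <- augment_pair(rs, base)
  }
  feats <- vector("list", length(variants))
  labs <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    pyr <- backbone_forward(variants[[i]]$pixels, backbone)
    feats[[i]] <- sample_features(pyr, variants[[i]]$coords)
    labs[[i]] <- variants[[i]]$coords$label
  }
  list(features = do.call(rbind, feats), labels = unlist(labs))
}

#' Train the grid-point annotation model
#'
#' @param data A scene tibble (columns `image_id`, `annotation`, and `image`
#'   or `path`) as produced by [generate_scenes()] / [load_dataset()], or a
#'   dataset directory path.
#' @param scheme [label_scheme()] used to consolidate annotation labels.
#' @param config [backbone_config()]; use narrow widths for desk-scale runs.
#' @param epochs Head training epochs.
#' @param lr Peak learning rate of the one-cycle schedule.
#' @param n_augment Augmented variants per image added to the original.
#' @param seed Root seed for weight initialisation, augmentation and
#'   mini-batch order; identical seeds give identical models and traces.
#' @return A `grid_model` with the trunk weights, trained head, feature
#'   statistics and a per-epoch `loss_trace` tibble.
#' @export
train_grid_model <- function(data, scheme = catami_scheme(),
                             config = backbone_config(), epochs = 40L,
                             lr = 1e-3, n_augment = 2L, seed = 1L) {
  data <- resolve_scene_rows(data)
  local_seed(seed, {
    backbone <- init_backbone(config, seed = sample.int(.Machine$integer.max, 1L))
    feats <- list(); labs <- list()
    for (i in seq_len(nrow(data))) {
      row <- data[i, ]
      ann <- consolidate(row$annotation[[1]], scheme)
      if (nrow(ann) == 0L) {
        warn(paste0("image '", row$image_id, "' has no valid points after consolidation; skipped"))
        next
      }
      fz <- featurize_grid_image(row_pixels(row), ann, backbone, n_augment)
      feats[[length(feats) + 1L]] <- fz$features
      labs[[length(labs) + 1L]] <- fz$labels
    }
    if (length(feats) == 0L) abort_degenerate("no training images with valid points")
    X <- do.call(rbind, feats)
    y <- match(unlist(labs), scheme$classes)
    st <- standardize_fit(X)
    fit <- train_mlp(st$X, y, mode = "softmax", hidden = config$hidden_width,
                     epochs = epochs, lr = lr,
                     seed = sample.int(.Machine$integer.max, 1L))
    structure(list(backbone = backbone, head = fit$par,
                   classes = scheme$classes,
                   feat_stats = st[c("mu", "sd")],
                   config = config, loss_trace = fit$trace,
                   n_train_points = nrow(X), seed = as.integer(seed)),
              class = "grid_model")
  })
}

#' @export
print.grid_model <- function(x, ...) {
  cat("<grid_model> ", length(x$classes), " classes, ",
      length(x$feat_stats$mu), " features/point, trained on ",
      x$n_train_points, " points (seed ", x$seed, ")\n", sep = "")
  cat("final training loss: ", signif(utils::tail(x$loss_trace$loss, 1), 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.grid_model <- function(x, ...) x$loss_trace

#' @export
glance.grid_model <- function(x, ...) {
  tibble(n_classes = length(x$classes),
         n_features = length(x$feat_stats$mu),
         n_train_points = x$n_train_points,
         epochs = nrow(x$loss_trace),
         initial_loss = x$loss_trace$loss[1],
         final_loss = utils::tail(x$loss_trace$loss, 1),
         seed = x$seed)
}

#' Predict habitat labels at grid points
#'
#' The image is resized to the backbone input, the query coordinates are
#' carried through the same transform, and each point receives a normalised
#' score vector over the classes (scores sum to 1 per point); the predicted
#' label is the argmax. Inference is deterministic for fixed weights.
#'
#' @param image A [source_image()], an H x W x 3 array, or a PNG path.
#' @param model A trained [train_grid_model()] object.
#' @param coords Optional query tibble with 0-based `x`, `y` (and optionally
#'   `row`, `col`) in the image's own pixel frame; defaults to the image's
#'   full 8 x 8 grid.
#' @return A tibble `image_id, row, col, x, y, predicted_label, score_*`.
#' @export
predict_points <- function(image, model, coords = NULL) {
  if (!inherits(model, "grid_model") || is.null(model$head)) {
    abort_state("model is not a trained grid_model; train or load a checkpoint first")
  }
  px <- as_pixels(image)
  image_id <- if (inherits(image, "source_image")) image$image_id else "image"
  H <- dim(px)[1]; W <- dim(px)[2]
  if (is.null(coords)) coords <- grid_coordinates(W, H)
  cfg <- model$config
  rs <- resize_image(px, cfg$input_width, cfg$input_height)
  cin <- coords_to_input(coords$x, coords$y, W, H, cfg$input_width, cfg$input_height)
  pyr <- backbone_forward(rs, model$backbone)
  X <- sample_features(pyr, tibble(x = cin$x, y = cin$y))
  X <- standardize_apply(X, model$feat_stats)
  sc <- mlp_scores(model$head, X, "softmax")
  out <- tibble(
    image_id = image_id,
    row = if ("row" %in% names(coords)) coords$row else NA_integer_,
    col = if ("col" %in% names(coords)) coords$col else NA_integer_,
    x = coords$x, y = coords$y,
    predicted_label = model$classes[max.col(sc, ties.method = "first")])
  for (k in seq_along(model$classes)) out[[paste0("score_", k)]] <- sc[, k]
  out
}

#' Evaluate a grid model on held-out scenes
#'
#' @param model A trained [train_grid_model()].
#' @param data Scene tibble or dataset directory of held-out images.
#' @param scheme [label_scheme()] for consolidating the reference labels.
#' @return List with `predictions` (tibble over all points) and `report`
#'   (a [metrics_report()]).
#' @export
evaluate_grid_model <- function(model, data, scheme = catami_scheme()) {
  data <- resolve_scene_rows(data)
  preds <- vector("list", nrow(data)); truths <- vector("list", nrow(data))
  for (i in seq_len(nrow(data))) {
    row <- data[i, ]
    ann <- consolidate(row$annotation[[1]], scheme)
    if (nrow(ann) == 0L) next
    img <- source_image(row$image_id, row_pixels(row))
    p <- predict_points(img, model, coords = ann[, c("row", "col", "x", "y")])
    preds[[i]] <- p
    truths[[i]] <- ann$label
  }
  predictions <- dplyr::bind_rows(preds)
  truth <- unlist(truths)
  report <- metrics_report(truth, predictions$predicted_label, scheme,
                           seed = model$seed)
  list(predictions = predictions, report = report)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are single files with a versioned header; both the grid and
#' the patch model round-trip exactly.
#'
#' @param model A `grid_model` or `patch_model`.
#' @param path Destination file.
#' @return `path` (save) or the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  if (!inherits(model, c("grid_model", "patch_model"))) {
    abort_state("only grid_model / patch_model objects can be checkpointed")
  }
  saveRDS(list(format = "benthoscan_checkpoint", version = 1L,
               model_class = class(model)[1], payload = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) abort_state(paste0("checkpoint not found: ", path))
  ck <- readRDS(path)
  if (!identical(ck$format, "benthoscan_checkpoint")) {
    abort_state("file is not a benthoscan checkpoint")
  }
  if (ck$version > 1L) abort_state("checkpoint written by a newer format version")
  ck$payload
}
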