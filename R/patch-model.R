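# Image-level presence/absence model. Each image contributes three large
# overlapping patches (left, centre, right); a patch's reference label is a
# 4-long presence vector aggregated from the annotated points it contains.
# Patches are resized to a square model input, pushed through the residual
# trunk, average+max pooled per block, and scored by a sigmoid head trained
# with binary cross-entropy (one independent output per class). Training is
# two-stage: a low-resolution stage followed by fine-tuning at doubled input
# resolution.

#' Patch extraction specification
#'
#' @param patch_size Square patch side in pixels (default 880). Images
#'   smaller than the patch in either dimension fall back to
#'   `min(width, height)` with a warning.
#' @param resize_stage1,resize_stage2 Model input sides for the two training
#'   stages (default 224 then 448; prediction runs at the stage-2 size).
#' @param threshold Decision threshold on the per-class sigmoid score.
#' @return A `patch_spec` object.
#' @export
patch_spec <- function(patch_size = 880L, resize_stage1 = 224L,
                       resize_stage2 = 448L, threshold = 0.5) {
  if (!is_count(patch_size)) abort_config("patch_size must be a positive integer")
  if (threshold < 0 || threshold > 1) abort_config("threshold must be in [0, 1]")
  structure(list(patch_size = as.integer(patch_size),
                 layout = c("left", "centre", "right"),
                 resize_stage1 = as.integer(resize_stage1),
                 resize_stage2 = as.integer(resize_stage2),
                 threshold = threshold),
            class = "patch_spec")
}

image_dims <- function(image) {
  if (is.numeric(image) && length(image) == 2L && is.null(dim(image))) {
    return(list(width = as.integer(image[1]), height = as.integer(image[2])))
  }
  px <- as_pixels(image)
  list(width = dim(px)[2], height = dim(px)[1])
}

#' Three overlapping patch geometries for an image
#'
#' The left patch is flush to `x = 0`, the right patch flush to
#' `x = W - size`, the centre patch at `x = floor((W - size) / 2)`; all are
#' vertically centred. The three patches overlap whenever `3 * size > W` and
#' their union spans the full image width whenever `W <= 3 * size`.
#'
#' @param image A [source_image()], pixel array, path, or a numeric
#'   `c(width, height)` pair.
#' @param spec A [patch_spec()].
#' @return Tibble with columns `position`, `x0`, `y0`, `size`.
#' @export
extract_patches <- function(image, spec = patch_spec()) {
  stopifnot(inherits(spec, "patch_spec"))
  d <- image_dims(image)
  size <- spec$patch_size
  if (size > d$width || size > d$height) {
    size <- min(d$width, d$height)
    warn(paste0("image (", d$width, "x", d$height, ") smaller than the ",
                spec$patch_size, " px patch; shrinking patches to ", size, " px"))
  }
  y0 <- as.integer(floor((d$height - size) / 2))
  tibble(position = spec$layout,
         x0 = as.integer(c(0L, floor((d$width - size) / 2), d$width - size)),
         y0 = y0, size = as.integer(size))
}

crop_patch <- function(px, x0, y0, size) {
  px[y0 + seq_len(size), x0 + seq_len(size), , drop = FALSE]
}

#' Aggregate point annotations into a patch presence vector
#'
#' `presence[k]` is `TRUE` iff at least one annotated point of class `k`
#' falls inside the half-open patch rectangle
#' `[x0, x0 + size) x [y0, y0 + size)`.
#'
#' @param ann Consolidated annotation tibble for one image.
#' @param patch One-row patch geometry (`x0`, `y0`, `size`), e.g. a row of
#'   [extract_patches()].
#' @param classes Class order of the output vector.
#' @return Named logical vector over `classes`, with attribute `n_points`
#'   (number of annotated points inside the patch); a patch containing no
#'   points warns and returns all-`FALSE`.
#' @export
aggregate_presence <- function(ann, patch, classes = BENTHIC_CLASSES) {
  bad <- setdiff(unique(ann$label), classes)
  if (length(bad)) {
    abort_schema(paste0("annotation labels not consolidated to the class set: ",
                        paste(bad, collapse = ", ")))
  }
  inside <- ann$x >= patch$x0 & ann$x < patch$x0 + patch$size &
    ann$y >= patch$y0 & ann$y < patch$y0 + patch$size
  if (!any(inside)) {
    warn(paste0("patch at (", patch$x0, ",", patch$y0, ") contains no annotated points"))
  }
  out <- classes %in% ann$label[inside]
  names(out) <- classes
  attr(out, "n_points") <- sum(inside)
  out
}

# Photometric/geometric augmentation for a square patch; presence labels are
# patch-level, so they are invariant under these transforms.
augment_patch <- function(px, max_angle = 10) {
  H <- dim(px)[1]; W <- dim(px)[2]
  if (runif(1) < 0.5) px <- px[, W:1, , drop = FALSE]
  if (runif(1) < 0.5) px <- px[H:1, , , drop = FALSE]
  px <- rotate_image(px, runif(1, -max_angle, max_angle))
  frac <- runif(1, 0.9, 1)                       # random crop, re-expanded
  cs <- max(8L, floor(frac * min(H, W)))
  x0 <- sample.int(W - cs + 1L, 1L) - 1L
  y0 <- sample.int(H - cs + 1L, 1L) - 1L
  px <- crop_patch(px, x0, y0, cs)
  px <- resize_image(px, W, H)
  clamp(px * runif(1, 0.9, 1.1) + runif(1, -15, 15), 0, 255)
}

# Pooled trunk features of one patch at a given model input side.
featurize_patch <- function(px, backbone, side) {
  rs <- resize_image(px, side, side)
  bb <- backbone
  bb$config$input_width <- as.integer(side)
  bb$config$input_height <- as.integer(side)
  pyr <- backbone_forward(rs, bb)
  unlist(lapply(pyr$blocks, global_pool), use.names = FALSE)
}

patch_training_table <- function(data, scheme, spec) {
  data <- resolve_scene_rows(data)
  rows <- vector("list", nrow(data))
  for (i in seq_len(nrow(data))) {
    row <- data[i, ]
    ann <- consolidate(row$annotation[[1]], scheme)
    px <- row_pixels(row)
    geoms <- extract_patches(c(dim(px)[2], dim(px)[1]), spec)
    pres <- t(vapply(seq_len(nrow(geoms)),
                     function(j) aggregate_presence(ann, geoms[j, ], scheme$classes),
                     logical(length(scheme$classes))))
    rows[[i]] <- dplyr::mutate(geoms, image_id = row$image_id, .before = 1L)
    rows[[i]]$presence <- lapply(seq_len(nrow(geoms)), function(j) pres[j, ])
    rows[[i]]$pixels <- lapply(seq_len(nrow(geoms)),
                               function(j) crop_patch(px, geoms$x0[j], geoms$y0[j], geoms$size[j]))
  }
  dplyr::bind_rows(rows)
}

#' Train the image-level patch presence model
#'
#' Stage 1 trains the presence head on patches resized to
#' `spec$resize_stage1`; stage 2 continues training (fine-tunes) on features
#' extracted at `spec$resize_stage2`, the resolution also used at prediction
#' time. The loss is binary cross-entropy, averaged over all four class
#' outputs so every habitat type carries equal weight.
#'
#' @param data Scene tibble or dataset directory (as for
#'   [train_grid_model()]).
#' @param scheme [label_scheme()] used to consolidate annotations.
#' @param spec [patch_spec()] geometry and resolutions.
#' @param config [backbone_config()] of the trunk (square input is implied;
#'   `input_width`/`input_height` are overridden per stage).
#' @param epochs_stage1,epochs_stage2 Head epochs per stage.
#' @param lr Peak learning rate.
#' @param n_augment Augmented variants per patch in stage 1.
#' @param seed Root seed; identical seeds give identical traces.
#' @return A `patch_model` with a staged `loss_trace`.
#' @export
train_patch_model <- function(data, scheme = catami_scheme(),
                              spec = patch_spec(),
                              config = backbone_config(),
                              epochs_stage1 = 30L, epochs_stage2 = 15L,
                              lr = 1e-3, n_augment = 1L, seed = 1L) {
  local_seed(seed, {
    samples <- patch_training_table(data, scheme, spec)
    pres <- do.call(rbind, samples$presence)
    never <- scheme$classes[colSums(pres) == 0L]
    if (length(never)) {
      warn(paste0("class(es) never present in training patches: ",
                  paste(never, collapse = ", "), "; their recall is undefined"))
    }
    backbone <- init_backbone(config, seed = sample.int(.Machine$integer.max, 1L))
    f1 <- list(); y1 <- list()
    for (i in seq_len(nrow(samples))) {
      px <- samples$pixels[[i]]
      f1[[length(f1) + 1L]] <- featurize_patch(px, backbone, spec$resize_stage1)
      y1[[length(y1) + 1L]] <- samples$presence[[i]]
      if (n_augment > 0L) {
        for (a in seq_len(n_augment)) {
          f1[[length(f1) + 1L]] <- featurize_patch(augment_patch(px), backbone,
                                                   spec$resize_stage1)
          y1[[length(y1) + 1L]] <- samples$presence[[i]]
        }
      }
    }
    X1 <- do.call(rbind, f1)
    Y1 <- do.call(rbind, lapply(y1, as.numeric))
    st <- standardize_fit(X1)
    fit1 <- train_mlp(st$X, Y1, mode = "sigmoid", hidden = config$hidden_width,
                      epochs = epochs_stage1, lr = lr,
                      seed = sample.int(.Machine$integer.max, 1L))
    # stage 2: same head, features recomputed at the higher resolution
    X2 <- t(vapply(samples$pixels,
                   function(px) featurize_patch(px, backbone, spec$resize_stage2),
                   numeric(ncol(X1))))
    Y2 <- do.call(rbind, lapply(samples$presence, as.numeric))
    fit2 <- train_mlp(standardize_apply(X2, st), Y2, mode = "sigmoid",
                      hidden = config$hidden_width, epochs = epochs_stage2,
                      lr = lr / 2, par = fit1$par,
                      seed = sample.int(.Machine$integer.max, 1L),
                      trace_offset = epochs_stage1)
    trace <- dplyr::bind_rows(
      dplyr::mutate(fit1$trace, stage = 1L),
      dplyr::mutate(fit2$trace, stage = 2L))
    structure(list(backbone = backbone, head = fit2$par,
                   classes = scheme$classes, spec = spec,
                   feat_stats = st[c("mu", "sd")], config = config,
                   loss_trace = trace, n_train_patches = nrow(samples),
                   seed = as.integer(seed)),
              class = "patch_model")
  })
}

#' @export
print.patch_model <- function(x, ...) {
  cat("<patch_model> ", length(x$classes), " classes, trained on ",
      x$n_train_patches, " patches (seed ", x$seed, ")\n", sep = "")
  cat("final training loss: ", signif(utils::tail(x$loss_trace$loss, 1), 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.patch_model <- function(x, ...) x$loss_trace

#' @export
glance.patch_model <- function(x, ...) {
  tibble(n_classes = length(x$classes),
         n_train_patches = x$n_train_patches,
         epochs = nrow(x$loss_trace),
         initial_loss = x$loss_trace$loss[1],
         final_loss = utils::tail(x$loss_trace$loss, 1),
         seed = x$seed)
}

#' Predict class presence for one patch
#'
#' @param pixels Square-ish patch pixel array in \[0, 255\].
#' @param model A trained [train_patch_model()] object.
#' @param threshold Decision threshold; defaults to the model's
#'   `spec$threshold`. Scores lie in \[0, 1\] and `present = score >=
#'   threshold`, so raising the threshold never adds a positive.
#' @return Tibble with one row per class: `class`, `score`, `present`.
#' @export
predict_presence <- function(pixels, model, threshold = NULL) {
  if (!inherits(model, "patch_model") || is.null(model$head)) {
    abort_state("model is not a trained patch_model; train or load a checkpoint first")
  }
  threshold <- threshold %||% model$spec$threshold
  f <- featurize_patch(as_pixels3(pixels), model$backbone, model$spec$resize_stage2)
  X <- standardize_apply(matrix(f, 1L), model$feat_stats)
  sc <- as.numeric(mlp_scores(model$head, X, "sigmoid"))
  tibble(class = model$classes, score = sc, present = sc >= threshold)
}

as_pixels3 <- function(pixels) {
  if (inherits(pixels, "source_image")) return(pixels$pixels)
  if (is.array(pixels) && length(dim(pixels)) == 3L) return(pixels)
  abort_schema("patch pixels must be an H x W x 3 array")
}

#' Predict presence over an image's three patches
#'
#' @param image A [source_image()], pixel array or path.
#' @param model A trained patch model.
#' @param threshold Decision threshold (default from the model spec).
#' @return Wide tibble, one row per patch:
#'   `image_id, position, x0, y0, p_sub, p_ma, p_sg, p_reef` plus four score
#'   columns.
#' @export
predict_image_patches <- function(image, model, threshold = NULL) {
  px <- as_pixels(image)
  image_id <- if (inherits(image, "source_image")) image$image_id else "image"
  geoms <- extract_patches(c(dim(px)[2], dim(px)[1]), model$spec)
  rows <- lapply(seq_len(nrow(geoms)), function(j) {
    p <- predict_presence(crop_patch(px, geoms$x0[j], geoms$y0[j], geoms$size[j]),
                          model, threshold)
    out <- tibble(image_id = image_id, position = geoms$position[j],
                  x0 = geoms$x0[j], y0 = geoms$y0[j])
    pcols <- setNames(as.list(p$present), c("p_sub", "p_ma", "p_sg", "p_reef"))
    scols <- setNames(as.list(p$score), paste0("score_", seq_along(p$score)))
    dplyr::bind_cols(out, as_tibble(pcols), as_tibble(scols))
  })
  dplyr::bind_rows(rows)
}

#' Evaluate a patch model on held-out scenes
#'
#' @param model A trained [train_patch_model()].
#' @param data Scene tibble or dataset directory.
#' @param scheme [label_scheme()].
#' @param threshold Decision threshold (default from the model spec).
#' @return List with `predictions` (patch-level truth and predictions) and
#'   `metrics` (a [presence_metrics()] report).
#' @export
evaluate_patch_model <- function(model, data, scheme = catami_scheme(),
                                 threshold = NULL) {
  samples <- patch_training_table(resolve_scene_rows(data), scheme, model$spec)
  truth <- do.call(rbind, samples$presence)
  pred <- matrix(NA, nrow(samples), length(model$classes))
  score <- matrix(NA_real_, nrow(samples), length(model$classes))
  for (i in seq_len(nrow(samples))) {
    p <- predict_presence(samples$pixels[[i]], model, threshold)
    pred[i, ] <- p$present
    score[i, ] <- p$score
  }
  metrics <- presence_metrics(truth, pred, classes = model$classes)
  predictions <- dplyr::select(samples, "image_id", "position", "x0", "y0")
  for (k in seq_along(model$classes)) {
    predictions[[paste0("true_", k)]] <- truth[, k]
    predictions[[paste0("pred_", k)]] <- pred[, k]
    predictions[[paste0("score_", k)]] <- score[, k]
  }
  list(predictions = predictions, metrics = metrics)
}
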