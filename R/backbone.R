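# Residual backbone for the grid-point model. The stem downsamples by 4; the
# four residual stages use spatial strides (1, 2, 1, 1), so the cumulative
# downsampling factors after blocks 1-4 are 4, 8, 8, 8: late stages keep
# spatial resolution so that a 448 x 224 input yields a 56 x 28 final map and
# each feature cell corresponds to an 8 x 8 pixel region of the input.

#' Backbone configuration for the grid-point model
#'
#' @param input_width,input_height Model input size in pixels; images are
#'   resized to this before the forward pass (default 448 x 224).
#' @param channel_widths Output channels of residual blocks 1-4. The default
#'   matches the standard 50-layer residual network widths; narrow widths
#'   (e.g. `c(16, 32, 64, 128)`) give a desk-scale backbone.
#' @param units Number of bottleneck units per block.
#' @param block_strides Per-block spatial strides; the default `c(1, 2, 1, 1)`
#'   keeps blocks 3 and 4 at stride 1 (no late downsampling).
#' @param stem_width Channels out of the 7 x 7 stem convolution.
#' @param attention_placement One of `"after_block4"` (default),
#'   `"after_block3"`, `"both"`, `"none"`.
#' @param attn_dim Projection width of the self-attention module.
#' @param hidden_width Width of the hidden fully connected layer of the
#'   per-point classifier head.
#' @param pretrained If `TRUE`, error: no pretrained weights are bundled;
#'   load a saved checkpoint instead.
#' @return A `backbone_config` object.
#' @export
backbone_config <- function(input_width = 448L, input_height = 224L,
                            channel_widths = c(256L, 512L, 1024L, 2048L),
                            units = c(3L, 4L, 6L, 3L),
                            block_strides = c(1L, 2L, 1L, 1L),
                            stem_width = max(8L, channel_widths[1] %/% 4L),
                            attention_placement = c("after_block4", "after_block3",
                                                    "both", "none"),
                            attn_dim = max(8L, channel_widths[4] %/% 8L),
                            hidden_width = 512L,
                            pretrained = FALSE) {
  attention_placement <- match.arg(attention_placement)
  if (length(channel_widths) != 4L || length(units) != 4L || length(block_strides) != 4L) {
    abort_config("channel_widths, units and block_strides must each have length 4")
  }
  if (any(block_strides < 1)) abort_config("block strides must be >= 1")
  if (isTRUE(pretrained)) {
    abort_config("no pretrained backbone weights are bundled; use load_checkpoint() on a saved model")
  }
  structure(list(input_width = as.integer(input_width),
                 input_height = as.integer(input_height),
                 channel_widths = as.integer(channel_widths),
                 units = as.integer(units),
                 block_strides = as.integer(block_strides),
                 stem_width = as.integer(stem_width),
                 attention_placement = attention_placement,
                 attn_dim = as.integer(attn_dim),
                 hidden_width = as.integer(hidden_width),
                 pretrained = FALSE),
            class = "backbone_config")
}

#' Cumulative downsampling factors of a backbone configuration
#'
#' The stem contributes a factor of 4; each block multiplies by its stride.
#'
#' @param config A [backbone_config()].
#' @return Integer vector of 4 cumulative factors (default 4, 8, 8, 8).
#' @export
cumulative_factors <- function(config) {
  as.integer(4L * cumprod(config$block_strides))
}

# One bottleneck unit: 1x1 reduce -> 3x3 (carries the stride) -> 1x1 expand,
# with a projection shortcut when shape changes.
init_unit <- function(cin, cout, stride) {
  mid <- max(4L, cout %/% 4L)
  u <- list(reduce = init_conv(1L, 1L, cin, mid),
            conv = init_conv(3L, 3L, mid, mid),
            expand = init_conv(1L, 1L, mid, cout),
            stride = as.integer(stride))
  if (cin != cout || stride != 1L) u$proj <- init_conv(1L, 1L, cin, cout)
  u
}

forward_unit <- function(x, u) {
  h <- relu(conv2d(x, u$reduce$w, u$reduce$b))
  h <- relu(conv2d(h, u$conv$w, u$conv$b, stride = u$stride))
  h <- conv2d(h, u$expand$w, u$expand$b)
  s <- if (is.null(u$proj)) {
    x
  } else {
    conv2d(x, u$proj$w, u$proj$b, stride = u$stride)
  }
  relu(h + s)
}

#' Initialise backbone weights
#'
#' He-normal random initialisation of the stem, the four residual stages and
#' any attention modules the placement calls for. Deterministic for a fixed
#' seed.
#'
#' @param config A [backbone_config()].
#' @param seed Integer seed.
#' @return A `backbone_weights` object.
#' @export
init_backbone <- function(config, seed = 1L) {
  stopifnot(inherits(config, "backbone_config"))
  local_seed(seed, {
    stem <- init_conv(7L, 7L, 3L, config$stem_width)
    blocks <- vector("list", 4L)
    cin <- config$stem_width
    for (b in 1:4) {
      cout <- config$channel_widths[b]
      us <- vector("list", config$units[b])
      for (j in seq_len(config$units[b])) {
        us[[j]] <- init_unit(cin, cout, if (j == 1L) config$block_strides[b] else 1L)
        cin <- cout
      }
      blocks[[b]] <- us
    }
    attn <- list()
    pl <- config$attention_placement
    if (pl %in% c("after_block3", "both")) {
      attn$block3 <- init_attention(config$channel_widths[3], config$attn_dim)
    }
    if (pl %in% c("after_block4", "both")) {
      attn$block4 <- init_attention(config$channel_widths[4], config$attn_dim)
    }
    structure(list(stem = stem, blocks = blocks, attention = attn,
                   config = config, seed = as.integer(seed)),
              class = "backbone_weights")
  })
}

#' Initialise a self-attention module
#'
#' Single-head scaled dot-product self-attention over the flattened spatial
#' positions of a feature map, with a residual (additive) connection back to
#' the input. Queries/keys/values are projected to `dim` channels and the
#' attended values are projected back to `channels`.
#'
#' @param channels Feature-map channels the module operates on.
#' @param dim Projection width.
#' @return An `attention_weights` object.
#' @export
init_attention <- function(channels, dim) {
  sd <- 1 / sqrt(channels)
  structure(list(
    wq = matrix(rnorm(channels * dim, sd = sd), channels, dim),
    wk = matrix(rnorm(channels * dim, sd = sd), channels, dim),
    wv = matrix(rnorm(channels * dim, sd = sd), channels, dim),
    wo = matrix(rnorm(dim * channels, sd = 1 / sqrt(dim)), dim, channels),
    dim = as.integer(dim)), class = "attention_weights")
}

#' Apply spatial self-attention to a feature map
#'
#' Every spatial position attends over all positions of the flattened grid;
#' the output is `x + softmax(QK' / sqrt(d)) V Wo`, reshaped to the input
#' shape. Output therefore depends on all spatial positions.
#'
#' @param feat H x W x C feature map.
#' @param weights An [init_attention()] object (its `channels` must match C).
#' @return Feature map of identical shape.
#' @export
apply_attention <- function(feat, weights) {
  stopifnot(inherits(weights, "attention_weights"))
  d <- dim(feat)
  if (nrow(weights$wq) != d[3]) {
    abort(paste0("attention expects ", nrow(weights$wq), " channels, got ", d[3]),
          class = "benthoscan_shape_error")
  }
  m <- matrix(feat, d[1] * d[2], d[3])
  q <- m %*% weights$wq
  k <- m %*% weights$wk
  v <- m %*% weights$wv
  s <- q %*% t(k) / sqrt(weights$dim)
  s <- exp(s - apply(s, 1L, max))
  p <- s / rowSums(s)
  array(m + (p %*% v) %*% weights$wo, d)
}

#' Forward pass through the backbone
#'
#' @param pixels H x W x 3 array in \[0, 255\]; its size must equal the
#'   configured input size.
#' @param backbone A [init_backbone()] object.
#' @return A `feature_pyramid`: list with `blocks` (four H x W x C arrays),
#'   `factors` (cumulative downsampling per block) and `input_size`
#'   (width, height).
#' @export
backbone_forward <- function(pixels, backbone) {
  stopifnot(inherits(backbone, "backbone_weights"))
  cfg <- backbone$config
  d <- dim(pixels)
  if (d[1] != cfg$input_height || d[2] != cfg$input_width) {
    abort(paste0("input is ", d[2], "x", d[1], " but backbone expects ",
                 cfg$input_width, "x", cfg$input_height),
          class = "benthoscan_shape_error")
  }
  x <- pixels / 127.5 - 1
  x <- relu(conv2d(x, backbone$stem$w, backbone$stem$b, stride = 2L))
  x <- max_pool3(x)
  blocks <- vector("list", 4L)
  for (b in 1:4) {
    for (u in backbone$blocks[[b]]) x <- forward_unit(x, u)
    if (b == 3L && !is.null(backbone$attention$block3)) {
      x <- apply_attention(x, backbone$attention$block3)
    }
    if (b == 4L && !is.null(backbone$attention$block4)) {
      x <- apply_attention(x, backbone$attention$block4)
    }
    blocks[[b]] <- x
  }
  structure(list(blocks = blocks, factors = cumulative_factors(cfg),
                 input_size = c(width = cfg$input_width, height = cfg$input_height)),
            class = "feature_pyramid")
}

#' @export
print.feature_pyramid <- function(x, ...) {
  cat("<feature_pyramid> input ", x$input_size[["width"]], "x",
      x$input_size[["height"]], "\n", sep = "")
  for (b in 1:4) {
    d <- dim(x$blocks[[b]])
    cat("  block ", b, ": ", d[2], "x", d[1], "x", d[3],
        " (factor ", x$factors[b], ")\n", sep = "")
  }
  invisible(x)
}

#' Rescale pixel coordinates to feature-map indices
#'
#' A pixel coordinate maps to the feature cell containing it:
#' `index = floor(coord / factor)`, clamped to the feature-map extent.
#'
#' @param coords Tibble or data frame with 0-based pixel columns `x`, `y`.
#' @param factor Cumulative downsampling factor (>= 1).
#' @param feat_width,feat_height Feature-map spatial extent in cells.
#' @return Tibble with 0-based feature indices `ix`, `iy`.
#' @export
rescale_coordinates <- function(coords, factor, feat_width, feat_height) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    abort_config("downsampling factor must be a positive scalar")
  }
  tibble(ix = clamp(as.integer(floor(coords$x / factor)), 0L, feat_width - 1L),
         iy = clamp(as.integer(floor(coords$y / factor)), 0L, feat_height - 1L))
}

#' Sample multi-block features at query coordinates
#'
#' For each query point, the feature vectors of residual blocks 1-4 at the
#' point's rescaled location are concatenated, giving one vector of length
#' `sum(channel_widths)` per point.
#'
#' @param pyramid A [backbone_forward()] feature pyramid.
#' @param coords Tibble with 0-based pixel columns `x`, `y` in input-space.
#' @return An N x sum(channels) numeric matrix, one row per query point.
#' @export
sample_features <- function(pyramid, coords) {
  stopifnot(inherits(pyramid, "feature_pyramid"))
  w_in <- pyramid$input_size[["width"]]; h_in <- pyramid$input_size[["height"]]
  if (any(coords$x < 0) || any(coords$x >= w_in) ||
      any(coords$y < 0) || any(coords$y >= h_in)) {
    abort(paste0("query coordinates outside the ", w_in, "x", h_in, " input"),
          class = "benthoscan_shape_error")
  }
  parts <- vector("list", 4L)
  for (b in 1:4) {
    fm <- pyramid$blocks[[b]]
    H <- dim(fm)[1]; W <- dim(fm)[2]
    idx <- rescale_coordinates(coords, pyramid$factors[b], W, H)
    lin <- idx$iy + 1L + idx$ix * H
    parts[[b]] <- matrix(fm, H * W, dim(fm)[3])[lin, , drop = FALSE]
  }
  do.call(cbind, parts)
}
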