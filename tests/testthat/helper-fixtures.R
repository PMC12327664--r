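# Shared fixtures, all generated in code.

classes4 <- c("1_UnCon Sub", "2_MA", "3_SG", "ReefStructure")

# Narrow random-init backbone for desk-scale tests.
tiny_backbone <- function(...) {
  backbone_config(channel_widths = c(8L, 16L, 32L, 64L), units = c(1L, 1L, 1L, 1L),
                  stem_width = 8L, attn_dim = 8L, hidden_width = 32L, ...)
}

# Small scenes render quickly while keeping all four textures.
tiny_scene_cfg <- function(seed = 1L, width = 256L, height = 160L,
                           class_weights = c(0.4, 0.3, 0.2, 0.1),
                           n_regions = 12L, fragmentation = 0.2, ...) {
  scene_config(width = width, height = height, class_weights = class_weights,
               n_regions = n_regions, fragmentation = fragmentation,
               seed = seed, ...)
}

# A random feature pyramid with the package's stride structure, built
# directly (no convolutions) for oracle tests of coordinate sampling.
random_pyramid <- function(input_width, input_height, widths = c(3L, 5L, 7L, 9L),
                           seed = 1L) {
  withr::with_seed(seed, {
    factors <- c(4L, 8L, 8L, 8L)
    blocks <- lapply(seq_len(4L), function(b) {
      h <- ceiling(input_height / factors[b])
      w <- ceiling(input_width / factors[b])
      array(rnorm(h * w * widths[b]), c(h, w, widths[b]))
    })
    structure(list(blocks = blocks, factors = factors,
                   input_size = c(width = input_width, height = input_height)),
              class = "feature_pyramid")
  })
}

# Independent oracle: per-point, per-block explicit lookup loop.
brute_force_sample <- function(pyramid, coords) {
  n <- nrow(coords)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    vec <- c()
    for (b in 1:4) {
      fm <- pyramid$blocks[[b]]
      f <- pyramid$factors[b]
      ix <- min(max(floor(coords$x[i] / f), 0), dim(fm)[2] - 1)
      iy <- min(max(floor(coords$y[i] / f), 0), dim(fm)[1] - 1)
      vec <- c(vec, fm[iy + 1, ix + 1, ])
    }
    rows[[i]] <- vec
  }
  do.call(rbind, rows)
}

# Independent oracle: presence via an explicit point-in-rectangle OR loop.
brute_force_presence <- function(ann, x0, y0, size, classes = classes4) {
  out <- setNames(rep(FALSE, length(classes)), classes)
  for (i in seq_len(nrow(ann))) {
    if (ann$x[i] >= x0 && ann$x[i] < x0 + size &&
        ann$y[i] >= y0 && ann$y[i] < y0 + size) {
      out[ann$label[i]] <- TRUE
    }
  }
  out
}

table1_scheme_path <- function() {
  system.file("extdata", "catami_consolidation.csv", package = "benthoscan")
}
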