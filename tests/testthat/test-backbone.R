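test_that("default stride schedule maps 448 x 224 to a 56 x 28 final map", {
  cfg <- tiny_backbone()   # narrow widths, default strides
  expect_identical(cumulative_factors(cfg), c(4L, 8L, 8L, 8L))
  bb <- init_backbone(cfg, seed = 1)
  px <- array(withr::with_seed(1, runif(224 * 448 * 3, 0, 255)), c(224, 448, 3))
  pyr <- backbone_forward(px, bb)
  d4 <- dim(pyr$blocks[[4]])
  expect_identical(d4[1:2], c(28L, 56L))        # height x width
  expect_identical(dim(pyr$blocks[[1]])[1:2], c(56L, 112L))
  expect_identical(dim(pyr$blocks[[2]])[1:2], c(28L, 56L))
  # each block's spatial dims equal ceiling(input / factor)
  for (b in 1:4) {
    expect_identical(dim(pyr$blocks[[b]])[1:2],
                     c(as.integer(ceiling(224 / pyr$factors[b])),
                       as.integer(ceiling(448 / pyr$factors[b]))))
  }
  expect_true(all(diff(pyr$factors) >= 0))
})

test_that("feature dims are input/8 exactly for inputs divisible by 8", {
  cfg <- tiny_backbone(input_width = 160L, input_height = 96L)
  bb <- init_backbone(cfg, seed = 2)
  px <- array(0, c(96, 160, 3))
  pyr <- backbone_forward(px, bb)
  expect_identical(dim(pyr$blocks[[4]])[1:2], c(12L, 20L))
  expect_error(backbone_forward(array(0, c(100, 160, 3)), bb),
               class = "benthoscan_shape_error")
})

test_that("coordinate rescaling is floor division with clamping", {
  q <- tibble::tibble(x = c(420, 0, 447, 455), y = c(100, 0, 223, 300))
  idx <- rescale_coordinates(q, 8, feat_width = 56L, feat_height = 28L)
  expect_identical(idx$ix, c(52L, 0L, 55L, 55L))   # 455 clamps to 55
  expect_identical(idx$iy, c(12L, 0L, 27L, 27L))
  expect_error(rescale_coordinates(q, 0, 56L, 28L),
               class = "benthoscan_config_error")
  # adjacent feature cells correspond to 8-pixel steps in the input
  xs <- tibble::tibble(x = seq(0, 447, by = 8), y = 0)
  ix <- rescale_coordinates(xs, 8, 56L, 28L)$ix
  expect_identical(ix, 0:55)
})

test_that("sample_features equals the brute-force per-point lookup", {
  pyr <- random_pyramid(448L, 224L, seed = 3)
  # origin gather
  one <- sample_features(pyr, tibble::tibble(x = 0, y = 0))
  expect_identical(as.numeric(one),
                   unlist(lapply(pyr$blocks, function(b) b[1, 1, ]),
                          use.names = FALSE))
  expect_identical(ncol(one), sum(c(3L, 5L, 7L, 9L)))
  # oracle equivalence over many random pyramids and query sets
  withr::with_seed(42, {
    for (rep in 1:8) {
      w <- in_h <- NULL
      in_w <- sample(c(448L, 320L, 64L), 1)
      in_h <- sample(c(224L, 160L, 64L), 1)
      p <- random_pyramid(in_w, in_h, widths = sample(2:6, 4, replace = TRUE),
                          seed = 100 + rep)
      q <- tibble::tibble(x = sample(0:(in_w - 1), 64, replace = TRUE),
                          y = sample(0:(in_h - 1), 64, replace = TRUE))
      expect_identical(sample_features(p, q), brute_force_sample(p, q))
    }
  })
  # out-of-bounds queries are a shape error
  expect_error(sample_features(pyr, tibble::tibble(x = 448, y = 0)),
               class = "benthoscan_shape_error")
})

test_that("feature vector length matches the standard 50-layer widths", {
  p <- random_pyramid(64L, 64L, widths = c(256L, 512L, 1024L, 2048L), seed = 9)
  v <- sample_features(p, tibble::tibble(x = 10, y = 10))
  expect_identical(ncol(v), 3840L)
})

test_that("attention preserves shape, is non-local, and reduces correctly", {
  withr::with_seed(5, {
    att <- init_attention(6L, 4L)
    fm <- array(rnorm(7 * 9 * 6), c(7, 9, 6))
    out <- apply_attention(fm, att)
    expect_identical(dim(out), dim(fm))
    # degenerate 1 x 1 map: residual plus the value/output projection
    one <- array(rnorm(6), c(1, 1, 6))
    got <- apply_attention(one, att)
    m <- matrix(one, 1, 6)
    expect_equal(array(m + (m %*% att$wv) %*% att$wo, c(1, 1, 6)), got,
                 tolerance = 1e-12)
    # zeroing a distant cell changes the output at the queried cell
    fm2 <- fm
    fm2[7, 9, ] <- 0
    out2 <- apply_attention(fm2, att)
    expect_gt(max(abs(out2[1, 1, ] - out[1, 1, ])), 0)
    # channel mismatch is a shape error
    expect_error(apply_attention(array(0, c(3, 3, 5)), att),
                 class = "benthoscan_shape_error")
  })
})

test_that("attention placement 'none' leaves the pyramid unchanged", {
  cfg_none <- tiny_backbone(attention_placement = "none",
                            input_width = 160L, input_height = 96L)
  cfg_att <- tiny_backbone(attention_placement = "after_block4",
                           input_width = 160L, input_height = 96L)
  px <- array(withr::with_seed(8, runif(96 * 160 * 3, 0, 255)), c(96, 160, 3))
  bb_n <- init_backbone(cfg_none, seed = 31)
  pyr_n <- backbone_forward(px, init_backbone(cfg_none, seed = 31))
  expect_identical(backbone_forward(px, bb_n)$blocks[[4]], pyr_n$blocks[[4]])
  # with attention enabled block 4 differs from the plain trunk output
  bb_a <- init_backbone(cfg_att, seed = 31)
  bb_a_stripped <- bb_a
  bb_a_stripped$attention <- list()
  with_att <- backbone_forward(px, bb_a)$blocks[[4]]
  without <- backbone_forward(px, bb_a_stripped)$blocks[[4]]
  expect_gt(max(abs(with_att - without)), 0)
})

test_that("pretrained weights are not silently invented", {
  expect_error(backbone_config(pretrained = TRUE),
               class = "benthoscan_config_error")
})
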