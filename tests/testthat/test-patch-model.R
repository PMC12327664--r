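test_that("three overlapping patches follow the flush/centred layout", {
  g <- extract_patches(c(1920, 1080), patch_spec(880))
  expect_identical(g$position, c("left", "centre", "right"))
  expect_identical(g$x0, c(0L, 520L, 1040L))
  expect_identical(unique(g$y0), 100L)
  expect_identical(unique(g$size), 880L)
  # overlap iff 3 * size > W; union spans the width when W <= 3 * size
  expect_true(3 * 880 > 1920)
  expect_identical(min(g$x0), 0L)
  expect_identical(max(g$x0 + g$size), 1920L)
  covered <- sort(unique(unlist(lapply(seq_len(3), function(j) g$x0[j]:(g$x0[j] + g$size[j] - 1)))))
  expect_identical(covered, 0:1919)
})

test_that("degenerate widths give identical patches and small images shrink", {
  g <- extract_patches(c(880, 900), patch_spec(880))
  expect_identical(unique(g$x0), 0L)
  expect_identical(nrow(dplyr::distinct(g[, c("x0", "y0", "size")])), 1L)
  expect_warning(g2 <- extract_patches(c(400, 300), patch_spec(880)),
                 "shrinking")
  expect_identical(unique(g2$size), 300L)
})

test_that("presence aggregation matches the worked single-patch example", {
  ann <- tibble::tibble(
    image_id = "img", row = 0:3, col = 0L,
    x = c(100L, 200L, 300L, 1500L),
    y = c(200L, 400L, 600L, 500L),
    label = c("1_UnCon Sub", "2_MA", "3_SG", "ReefStructure"))
  g <- extract_patches(c(1920, 1080), patch_spec(880))
  left <- aggregate_presence(ann, g[1, ])
  expect_identical(as.logical(left), c(TRUE, TRUE, TRUE, FALSE))
  # empty patch: all-false plus a warning, n_points flag 0
  far <- tibble::tibble(x0 = 1040L, y0 = 100L, size = 880L)
  ann2 <- ann[1:3, ]
  expect_warning(v <- aggregate_presence(ann2, far), "no annotated points")
  expect_identical(as.logical(v), rep(FALSE, 4))
  expect_identical(attr(v, "n_points"), 0L)
  # unconsolidated labels are rejected
  bad <- ann; bad$label[1] <- "Macroalgae"
  expect_error(aggregate_presence(bad, g[1, ]), class = "benthoscan_schema_error")
})

test_that("presence aggregation equals the brute-force point-in-rectangle OR", {
  withr::with_seed(23, {
    for (i in 1:100) {
      n <- sample(5:64, 1)
      W <- sample(200:800, 1); H <- sample(200:800, 1)
      ann <- tibble::tibble(
        image_id = "r", row = seq_len(n), col = 1L,
        x = sample(0:(W - 1), n, replace = TRUE),
        y = sample(0:(H - 1), n, replace = TRUE),
        label = sample(classes4, n, replace = TRUE))
      size <- sample(20:200, 1)
      x0 <- sample(0:(W - 10), 1); y0 <- sample(0:(H - 10), 1)
      patch <- tibble::tibble(x0 = x0, y0 = y0, size = size)
      got <- suppressWarnings(aggregate_presence(ann, patch))
      want <- brute_force_presence(ann, x0, y0, size)
      expect_identical(as.logical(got), unname(want))
    }
  })
})

test_that("presence labels are translation-consistent", {
  # shifting points and the patch origin together leaves presence unchanged
  withr::with_seed(29, {
    ann <- tibble::tibble(image_id = "t", row = 1:20, col = 1L,
                          x = sample(0:300, 20), y = sample(0:300, 20),
                          label = sample(classes4, 20, replace = TRUE))
    patch <- tibble::tibble(x0 = 50L, y0 = 60L, size = 120L)
    base <- suppressWarnings(aggregate_presence(ann, patch))
    for (shift in c(7L, 31L)) {
      ann2 <- dplyr::mutate(ann, x = x + shift, y = y + shift)
      patch2 <- dplyr::mutate(patch, x0 = x0 + shift, y0 = y0 + shift)
      expect_identical(as.logical(suppressWarnings(aggregate_presence(ann2, patch2))),
                       as.logical(base))
    }
  })
})

test_that("patch training produces a decreasing staged loss and deterministic traces", {
  scenes <- generate_scenes(tiny_scene_cfg(seed = 61), 6)
  spec <- patch_spec(patch_size = 140, resize_stage1 = 64, resize_stage2 = 96)
  cfg <- tiny_backbone()
  m1 <- suppressWarnings(train_patch_model(scenes, spec = spec, config = cfg,
                                           epochs_stage1 = 8, epochs_stage2 = 4,
                                           n_augment = 1, seed = 5))
  expect_s3_class(m1, "patch_model")
  expect_identical(nrow(m1$loss_trace), 12L)
  expect_identical(unique(m1$loss_trace$stage), c(1L, 2L))
  expect_lt(dplyr::last(m1$loss_trace$loss[m1$loss_trace$stage == 1]),
            m1$loss_trace$loss[1])
  m2 <- suppressWarnings(train_patch_model(scenes, spec = spec, config = cfg,
                                           epochs_stage1 = 8, epochs_stage2 = 4,
                                           n_augment = 1, seed = 5))
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$head, m2$head)

  # inference: determinism, score bounds, threshold limits and monotonicity
  px <- scenes$image[[1]]
  patch <- px[1:140, 1:140, ]
  p1 <- predict_presence(patch, m1)
  p2 <- predict_presence(patch, m1)
  expect_identical(p1, p2)
  expect_true(all(p1$score >= 0 & p1$score <= 1))
  expect_true(all(predict_presence(patch, m1, threshold = 0)$present))
  ths <- seq(0, 1, by = 0.1)
  n_pos <- vapply(ths, function(th) sum(predict_presence(patch, m1, th)$present),
                  numeric(1))
  expect_true(all(diff(n_pos) <= 0))

  # checkpoint round-trip reproduces predictions exactly
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m1, f)
  m3 <- load_checkpoint(f)
  expect_identical(predict_presence(patch, m3), p1)

  # untrained/unloaded model is a state error
  broken <- m1; broken$head <- NULL
  expect_error(predict_presence(patch, broken), class = "benthoscan_state_error")
})
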