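test_that("scene generation is deterministic and mask-consistent", {
  cfg <- tiny_scene_cfg(seed = 7)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$annotation, s2$annotation)
  expect_true(all(s1$mask %in% 0:3))
  # every grid label equals the mask value under it
  lab_from_mask <- classes4[s1$mask[cbind(s1$annotation$y + 1L,
                                          s1$annotation$x + 1L)] + 1L]
  expect_identical(s1$annotation$label, lab_from_mask)
})

test_that("a single-class scene labels every grid point with that class", {
  s <- generate_scene(tiny_scene_cfg(seed = 3, class_weights = c(1, 0, 0, 0)))
  expect_true(all(s$annotation$label == "1_UnCon Sub"))
  expect_true(all(s$mask == 0L))
})

test_that("pooled grid-label frequencies track the configured class weights", {
  w <- c(0.7, 0.15, 0.14, 0.01)
  labs <- unlist(lapply(1:60, function(i) {
    generate_scene(tiny_scene_cfg(seed = 1000 + i, width = 192, height = 128,
                                  class_weights = w, n_regions = 30))$annotation$label
  }))
  freq <- as.numeric(table(factor(labs, levels = classes4))) / length(labs)
  expect_true(all(abs(freq - w) < 0.05))
})

test_that("mean-colour features linearly separate substrate from macroalgae", {
  # guarantees the learning problem the models face is solvable
  sub <- generate_scene(tiny_scene_cfg(seed = 21, class_weights = c(1, 0, 0, 0)))
  ma <- generate_scene(tiny_scene_cfg(seed = 22, class_weights = c(0, 1, 0, 0)))
  cell_means <- function(scene) {
    px <- scene$image$pixels
    t(vapply(seq_len(nrow(scene$annotation)), function(i) {
      x <- scene$annotation$x[i]; y <- scene$annotation$y[i]
      xs <- pmax(1, x - 3):pmin(dim(px)[2], x + 4)
      ys <- pmax(1, y - 3):pmin(dim(px)[1], y + 4)
      c(mean(px[ys, xs, 1]), mean(px[ys, xs, 2]), mean(px[ys, xs, 3]))
    }, numeric(3)))
  }
  X <- rbind(cell_means(sub), cell_means(ma))
  y <- rep(c(0, 1), each = 64)
  fit <- suppressWarnings(stats::glm(y ~ X, family = stats::binomial()))
  acc <- mean((stats::fitted(fit) > 0.5) == y)
  expect_gt(acc, 0.9)
})

test_that("invalid scene configurations are rejected", {
  expect_error(scene_config(class_weights = c(0, 0, 0, 0)),
               class = "benthoscan_config_error")
  expect_error(scene_config(width = 32), class = "benthoscan_config_error")
  expect_error(scene_config(fragmentation = 2), class = "benthoscan_config_error")
})

test_that("generate_dataset writes a reproducible, complete dataset", {
  cfg <- tiny_scene_cfg(seed = 5, width = 128, height = 96, n_regions = 6)
  d1 <- withr::local_tempdir()
  m1 <- generate_dataset(cfg, 3, d1)
  expect_identical(m1$n_points, 192L)
  expect_length(m1$images, 3L)
  expect_true(file.exists(file.path(d1, "annotations.csv")))
  expect_true(all(file.exists(file.path(d1, vapply(m1$images, `[[`, "", "image")))))
  # single-image manifest
  d2 <- withr::local_tempdir()
  m2 <- generate_dataset(cfg, 1, d2)
  expect_length(m2$images, 1L)
  # identical config -> byte-identical manifest (and files)
  d3 <- withr::local_tempdir()
  generate_dataset(cfg, 3, d3)
  h1 <- tools::md5sum(file.path(d1, "manifest.json"))
  h3 <- tools::md5sum(file.path(d3, "manifest.json"))
  expect_identical(unname(h1), unname(h3))
  # mask PNGs round-trip the class indices
  msk <- benthoscan:::read_mask(file.path(d1, m1$images[[1]]$mask))
  expect_true(all(msk %in% 0:3))
  # loading the dataset recovers per-image annotations
  tb <- load_dataset(d1)
  expect_identical(nrow(tb), 3L)
  expect_identical(nrow(tb$annotation[[1]]), 64L)
  img <- read_image(tb$path[1])
  expect_identical(dim(img), c(96L, 128L, 3L))
})
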