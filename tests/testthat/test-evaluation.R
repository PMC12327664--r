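test_that("confusion matrix tallies match hand counts", {
  cm <- confusion(c("A", "A", "B"), c("A", "B", "B"), scheme = c("A", "B"))
  expect_identical(unclass(cm)[, ], matrix(c(1L, 0L, 1L, 1L), 2, 2,
                                           dimnames = dimnames(cm)))
  expect_equal(overall_accuracy(cm), 2 / 3)
  # perfect predictions give a diagonal matrix
  cmd <- confusion(classes4, classes4, classes4)
  expect_identical(sum(diag(unclass(cmd))), 4L)
  expect_identical(sum(cmd) - sum(diag(unclass(cmd))), 0L)
  # degenerate and malformed inputs
  expect_error(confusion(character(), character(), classes4),
               class = "benthoscan_degenerate_error")
  expect_error(confusion("A", c("A", "B"), c("A", "B")),
               class = "benthoscan_schema_error")
  expect_error(confusion("Z", "A", c("A", "B")), class = "benthoscan_schema_error")
})

test_that("precision and recall match hand arithmetic, with NA for 0/0", {
  cm <- confusion(c("A", "A", "B"), c("A", "B", "B"), scheme = c("A", "B"))
  pr <- precision_recall(cm)
  expect_equal(pr$precision[pr$class == "B"], 0.5)
  expect_equal(pr$recall[pr$class == "B"], 1.0)
  expect_equal(pr$precision[pr$class == "A"], 1.0)
  expect_equal(pr$recall[pr$class == "A"], 0.5)
  # diagonal matrix: all ones
  prd <- precision_recall(confusion(c("A", "B"), c("A", "B"), c("A", "B")))
  expect_true(all(prd$precision == 1) && all(prd$recall == 1))
  # class never predicted -> undefined precision, not zero
  cm2 <- confusion(c("A", "B"), c("A", "A"), c("A", "B"))
  pr2 <- precision_recall(cm2)
  expect_true(is.na(pr2$precision[pr2$class == "B"]))
  expect_false(is.na(pr2$recall[pr2$class == "B"]))
})

test_that("overall accuracy equals the mean per-point correctness", {
  withr::with_seed(13, {
    for (i in 1:10) {
      truth <- sample(classes4, 50, replace = TRUE)
      pred <- sample(classes4, 50, replace = TRUE)
      cm <- confusion(truth, pred, classes4)
      expect_equal(overall_accuracy(cm), mean(truth == pred))
      # permutation invariance
      o <- sample(50)
      expect_identical(unclass(confusion(truth[o], pred[o], classes4)),
                       unclass(cm))
    }
  })
})

test_that("patch-wise accuracy requires all classes simultaneously correct", {
  t_ <- rbind(c(TRUE, TRUE, TRUE, FALSE),
              c(TRUE, FALSE, FALSE, FALSE),
              c(FALSE, TRUE, TRUE, TRUE))
  p1 <- t_
  expect_equal(patchwise_accuracy(t_, p1), 1)
  p2 <- t_
  p2[2, 1] <- FALSE; p2[3, 4] <- FALSE
  expect_equal(patchwise_accuracy(t_, p2), 1 / 3)
  p3 <- t_
  p3[cbind(1:3, c(1, 2, 3))] <- !p3[cbind(1:3, c(1, 2, 3))]
  expect_equal(patchwise_accuracy(t_, p3), 0)
  expect_error(patchwise_accuracy(list(c(TRUE, FALSE)), list(TRUE)),
               class = "benthoscan_schema_error")
})

test_that("presence metrics match an enumerated two-patch toy", {
  truth <- rbind(c(TRUE, TRUE, FALSE, FALSE),
                 c(TRUE, FALSE, TRUE, FALSE))
  pred <- rbind(c(TRUE, FALSE, FALSE, FALSE),
                c(TRUE, TRUE, TRUE, FALSE))
  pm <- presence_metrics(truth, pred, classes4)
  # class 1: TP=2 -> precision 1, recall 1; class 2: TP=0,FP=1,FN=1 -> 0/0? no: precision 0/1=0, recall 0
  expect_equal(pm$per_class$precision, c(1, 0, 1, NA_real_))
  expect_equal(pm$per_class$recall, c(1, 0, 1, NA_real_))
  expect_equal(pm$element_accuracy, 6 / 8)
  expect_equal(pm$patchwise_accuracy, 0)
  # class absent from truth and predictions -> both undefined
  expect_true(is.na(pm$per_class$precision[4]) && is.na(pm$per_class$recall[4]))
  # perfect predictions
  pperf <- presence_metrics(truth, truth, classes4)
  expect_equal(pperf$element_accuracy, 1)
  expect_equal(pperf$patchwise_accuracy, 1)
})

test_that("patch-wise accuracy never exceeds element-wise accuracy", {
  withr::with_seed(17, {
    for (i in 1:25) {
      n <- sample(2:30, 1)
      t_ <- matrix(runif(n * 4) < 0.5, n, 4)
      p_ <- matrix(runif(n * 4) < 0.5, n, 4)
      pm <- presence_metrics(t_, p_, classes4)
      expect_lte(pm$patchwise_accuracy, pm$element_accuracy)
    }
  })
})

test_that("metrics reports serialise to JSON with stable content", {
  truth <- rep(classes4, times = c(10, 5, 4, 1))
  pred <- truth
  pred[c(1, 12)] <- c("2_MA", "3_SG")
  rep1 <- metrics_report(truth, pred, classes4, seed = 3L,
                         config = list(a = 1))
  expect_equal(rep1$overall_accuracy, 18 / 20)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep1, f1)
  write_metrics_json(rep1, f2)
  j1 <- jsonlite::read_json(f1)
  j2 <- jsonlite::read_json(f2)
  j1$timestamp <- j2$timestamp <- NULL
  expect_identical(j1, j2)
  expect_equal(j1$overall_accuracy, 0.9)
  expect_identical(j1$kind, "point_metrics")
})
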