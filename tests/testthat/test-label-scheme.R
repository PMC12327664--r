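test_that("the packaged consolidation maps seven originals onto four classes", {
  sch <- catami_scheme()
  expect_length(sch$mapping, 7L)
  expect_identical(sch$classes, classes4)
  expect_identical(unname(sch$mapping[["Sponge"]]), "ReefStructure")
  expect_identical(unname(sch$mapping[["Unconsolidated Substrate (Sand)"]]), "1_UnCon Sub")
  # every original maps to exactly one class; mapping and exclusions disjoint
  expect_false(anyDuplicated(names(sch$mapping)) > 0)
  expect_length(intersect(names(sch$mapping), sch$excluded), 0L)
})

test_that("class order is first-appearance order and extra synonyms do not add classes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("original_label,consolidated_label", "Seagrass,3_SG"), f)
  sch <- load_label_scheme(f)
  expect_identical(sch$classes, "3_SG")

  tb <- readr::read_csv(table1_scheme_path(), show_col_types = FALSE)
  tb <- rbind(tb, data.frame(original_label = "Bryozoa",
                             consolidated_label = "ReefStructure"))
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tb, f2)
  sch2 <- load_label_scheme(f2)
  expect_length(sch2$mapping, 8L)
  expect_length(sch2$classes, 4L)
})

test_that("malformed scheme files are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("original_label,consolidated_label", f)
  expect_error(load_label_scheme(f), class = "benthoscan_schema_error")
  writeLines(c("original_label,consolidated_label",
               "Sponge,ReefStructure", "Sponge,2_MA"), f)
  expect_error(load_label_scheme(f), "conflicting",
               class = "benthoscan_schema_error")
})

test_that("EXCLUDE sentinel rows populate the exclusion set", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("original_label,consolidated_label",
               "Seagrass,3_SG", "Fishes,EXCLUDE", "Unknown sp.,EXCLUDE"), f)
  sch <- load_label_scheme(f)
  expect_setequal(sch$excluded, c("Fishes", "Unknown sp."))
  expect_identical(sch$classes, "3_SG")
})

test_that("consolidation rewrites labels, drops exclusions, preserves order", {
  sch <- catami_scheme()
  ann <- grid_coordinates(448, 224)
  ann$image_id <- "img1"
  ann$label <- c(rep("Macroalgae", 60), rep("Hard Coral", 4))
  out <- consolidate(ann, sch)
  expect_identical(sum(out$label == "2_MA"), 60L)
  expect_identical(sum(out$label == "ReefStructure"), 4L)

  # fixed point: already-consolidated labels pass through
  out2 <- consolidate(out, sch)
  expect_identical(out2, out)

  # exclusions shrink the table, survivors keep their order
  sch2 <- label_scheme(sch$mapping, excluded = "Fishes")
  ann$label[c(10, 20)] <- "Fishes"
  out3 <- consolidate(ann, sch2)
  expect_identical(nrow(out3), 62L)
  expect_identical(out3$x, ann$x[-c(10, 20)])

  # unknown labels are named in the error together with the image
  ann$label[5] <- "Kraken"
  expect_error(consolidate(ann, sch2), "Kraken.*img1",
               class = "benthoscan_schema_error")
})

test_that("consolidation never invents labels outside the class set", {
  sch <- catami_scheme()
  withr::with_seed(11, {
    for (i in 1:20) {
      ann <- tibble::tibble(
        image_id = "z", row = 0L, col = 0L, x = 1L, y = 1L,
        label = sample(names(sch$mapping), 30, replace = TRUE))
      out <- consolidate(ann, sch)
      expect_true(all(out$label %in% sch$classes))
      expect_lte(nrow(out), nrow(ann))
    }
  })
})
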