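# Evaluation machinery: confusion matrix, per-class precision and recall,
# overall accuracy, and the patch model's presence metrics including
# patch-wise (all-classes-correct) accuracy. Undefined 0/0 ratios are
# reported as NA, never silently as 0.

#' Confusion matrix of true vs predicted labels
#'
#' Rows are true classes, columns predicted classes, in the scheme's class
#' order.
#'
#' @param truth,predicted Equal-length character vectors of class labels.
#' @param scheme A [label_scheme()], or a character vector of class names.
#' @return A `conf_mat`: integer matrix with class dimnames.
#' @export
confusion <- function(truth, predicted, scheme = catami_scheme()) {
  classes <- if (inherits(scheme, "label_scheme")) scheme$classes else as.character(scheme)
  if (length(truth) != length(predicted)) {
    abort_schema("truth and predicted must have equal length")
  }
  if (length(truth) == 0L) abort_degenerate("no labels to evaluate")
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) {
    abort_schema(paste0("labels outside the class set: ", paste(bad, collapse = ", ")))
  }
  tt <- factor(truth, levels = classes)
  pp <- factor(predicted, levels = classes)
  m <- table(true = tt, predicted = pp)
  structure(matrix(as.integer(m), length(classes), length(classes),
                   dimnames = list(true = classes, predicted = classes)),
            class = "conf_mat")
}

#' @export
print.conf_mat <- function(x, ...) {
  print(unclass(x))
  cat("overall accuracy:", signif(overall_accuracy(x), 4), "\n")
  invisible(x)
}

#' @export
tidy.conf_mat <- function(x, ...) {
  as_tibble(as.data.frame.table(unclass(x), responseName = "n"))
}

#' Overall accuracy from a confusion matrix
#'
#' @param cm A [confusion()] matrix.
#' @return Proportion of correctly classified points (trace / total).
#' @export
overall_accuracy <- function(cm) {
  sum(diag(unclass(cm))) / sum(cm)
}

#' Per-class precision and recall
#'
#' `precision_k = cm[k,k] / colsum_k`, `recall_k = cm[k,k] / rowsum_k`. A
#' class with no predicted (resp. true) instances has undefined precision
#' (resp. recall), reported as `NA`.
#'
#' @param cm A [confusion()] matrix.
#' @return Tibble with `class`, `precision`, `recall`, `support`.
#' @export
precision_recall <- function(cm) {
  m <- unclass(cm)
  tp <- diag(m)
  pred_n <- colSums(m)
  true_n <- rowSums(m)
  tibble(class = rownames(m),
         precision = unname(ifelse(pred_n > 0, tp / pred_n, NA_real_)),
         recall = unname(ifelse(true_n > 0, tp / true_n, NA_real_)),
         support = as.integer(unname(true_n)))
}

as_presence_matrix <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.list(x) && !is.matrix(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) != 1L) {
      abort_schema(paste0(what, ": presence vectors have unequal lengths"))
    }
    x <- do.call(rbind, x)
  }
  if (!is.matrix(x)) abort_schema(paste0(what, " must be a matrix or list of vectors"))
  storage.mode(x) <- "logical"
  x
}

#' Patch-wise accuracy
#'
#' Proportion of patches for which the presence or absence of all classes is
#' simultaneously correct.
#'
#' @param truth,predicted n x C logical matrices (or lists of equal-length
#'   logical vectors).
#' @return A proportion in \[0, 1\].
#' @export
patchwise_accuracy <- function(truth, predicted) {
  t_ <- as_presence_matrix(truth, "truth")
  p_ <- as_presence_matrix(predicted, "predicted")
  if (!all(dim(t_) == dim(p_))) abort_schema("truth and predicted shapes differ")
  if (nrow(t_) == 0L) abort_degenerate("no patches to evaluate")
  mean(rowSums(t_ == p_) == ncol(t_))
}

#' Presence/absence metrics for the patch model
#'
#' Element-wise accuracy pools all class-patch decisions
#' (`matching booleans / (C * n)`); per-class precision and recall treat each
#' class as an independent binary detector; patch-wise accuracy requires all
#' classes correct at once (and therefore can never exceed the element-wise
#' accuracy).
#'
#' @param truth,predicted n x C logical matrices (or lists of vectors).
#' @param classes Class names for the per-class rows.
#' @return A `presence_metrics` list with `per_class` (tibble),
#'   `element_accuracy` and `patchwise_accuracy`.
#' @export
presence_metrics <- function(truth, predicted, classes = BENTHIC_CLASSES) {
  t_ <- as_presence_matrix(truth, "truth")
  p_ <- as_presence_matrix(predicted, "predicted")
  if (!all(dim(t_) == dim(p_))) abort_schema("truth and predicted shapes differ")
  if (nrow(t_) == 0L) abort_degenerate("no patches to evaluate")
  if (ncol(t_) != length(classes)) abort_schema("presence width does not match class count")
  per <- purrr::map_dfr(seq_along(classes), function(k) {
    tp <- sum(t_[, k] & p_[, k]); fp <- sum(!t_[, k] & p_[, k])
    fn <- sum(t_[, k] & !p_[, k])
    tibble(class = classes[k],
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           accuracy = mean(t_[, k] == p_[, k]),
           support = sum(t_[, k]))
  })
  structure(list(per_class = per,
                 element_accuracy = mean(t_ == p_),
                 patchwise_accuracy = patchwise_accuracy(t_, p_),
                 n_patches = nrow(t_)),
            class = "presence_metrics")
}

#' @export
print.presence_metrics <- function(x, ...) {
  cat("<presence_metrics> ", x$n_patches, " patches\n", sep = "")
  cat("element-wise accuracy: ", signif(x$element_accuracy, 4),
      "; patch-wise accuracy: ", signif(x$patchwise_accuracy, 4), "\n", sep = "")
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.presence_metrics <- function(x, ...) x$per_class

#' @export
glance.presence_metrics <- function(x, ...) {
  tibble(element_accuracy = x$element_accuracy,
         patchwise_accuracy = x$patchwise_accuracy,
         n_patches = x$n_patches)
}

#' Build a metrics report for point-label predictions
#'
#' @param truth,predicted Equal-length label vectors.
#' @param scheme [label_scheme()] fixing the class order.
#' @param seed Seed recorded in the report for provenance.
#' @param config Optional configuration object; its fingerprint is embedded.
#' @return A `metrics_report`: confusion matrix, per-class tibble, overall
#'   accuracy, supports, config fingerprint and seed.
#' @export
metrics_report <- function(truth, predicted, scheme = catami_scheme(),
                           seed = NA_integer_, config = NULL) {
  cm <- confusion(truth, predicted, scheme)
  structure(list(confusion = cm,
                 per_class = precision_recall(cm),
                 overall_accuracy = overall_accuracy(cm),
                 n_points = sum(cm),
                 config_fingerprint = if (is.null(config)) NA_character_ else fingerprint(config),
                 seed = seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> ", x$n_points, " points, overall accuracy ",
      signif(x$overall_accuracy, 4), "\n", sep = "")
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @export
glance.metrics_report <- function(x, ...) {
  tibble(overall_accuracy = x$overall_accuracy, n_points = x$n_points,
         seed = x$seed)
}

#' Write a metrics report to JSON
#'
#' The JSON embeds the confusion matrix, per-class metrics, overall
#' accuracy, supports, the configuration fingerprint and seed, plus a
#' timestamp kept in its own field so that reports from identical runs are
#' comparable after dropping it.
#'
#' @param report A [metrics_report()] or [presence_metrics()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  if (inherits(report, "metrics_report")) {
    body <- list(kind = "point_metrics",
                 classes = rownames(report$confusion),
                 confusion = unclass(report$confusion),
                 per_class = report$per_class,
                 overall_accuracy = report$overall_accuracy,
                 n_points = report$n_points,
                 config_fingerprint = report$config_fingerprint,
                 seed = report$seed)
  } else if (inherits(report, "presence_metrics")) {
    body <- list(kind = "presence_metrics",
                 per_class = report$per_class,
                 element_accuracy = report$element_accuracy,
                 patchwise_accuracy = report$patchwise_accuracy,
                 n_patches = report$n_patches,
                 note = "element_accuracy pools all class-patch decisions; patchwise_accuracy requires all classes correct per patch")
  } else {
    abort_schema("report must be a metrics_report or presence_metrics")
  }
  body$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(body, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
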