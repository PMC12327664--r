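# Label consolidation: CATAMI-broad habitat labels are collapsed onto a small
# set of classes before modelling; rare categories can be excluded outright.

#' Construct a label scheme
#'
#' A label scheme maps original (e.g. CATAMI-broad) habitat labels onto the
#' consolidated classes used for modelling, and records which original labels
#' are excluded from modelling altogether.
#'
#' @param mapping Named character vector: `names()` are original labels,
#'   values are consolidated class names.
#' @param excluded Character vector of original labels dropped from modelling.
#' @return A `label_scheme` object with fields `mapping`, `classes` (in
#'   first-appearance order) and `excluded`.
#' @export
label_scheme <- function(mapping, excluded = character()) {
  if (length(mapping) == 0L) abort_schema("label scheme mapping is empty")
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    abort_schema("mapping must be a named character vector (original -> consolidated)")
  }
  dup <- names(mapping)[duplicated(names(mapping))]
  for (d in unique(dup)) {
    tg <- unique(mapping[names(mapping) == d])
    if (length(tg) > 1L) {
      abort_schema(paste0("original label '", d, "' maps to conflicting targets: ",
                          paste(tg, collapse = ", ")))
    }
  }
  mapping <- mapping[!duplicated(names(mapping))]
  excluded <- unique(as.character(excluded))
  both <- intersect(names(mapping), excluded)
  if (length(both) > 0L) {
    abort_schema(paste0("labels both mapped and excluded: ", paste(both, collapse = ", ")))
  }
  structure(
    list(mapping = mapping,
         classes = unique(unname(mapping)),
         excluded = excluded),
    class = "label_scheme"
  )
}

#' Load a label scheme from a two-column CSV file
#'
#' The file must have columns `original_label,consolidated_label`. Rows whose
#' consolidated label is the sentinel `EXCLUDE` mark original labels that are
#' dropped from modelling. Consolidated class order is first-appearance order
#' in the file.
#'
#' @param path Path to the mapping CSV.
#' @return A [label_scheme()].
#' @export
load_label_scheme <- function(path) {
  if (!file.exists(path)) abort_schema(paste0("label scheme file not found: ", path))
  tb <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("original_label", "consolidated_label")
  if (!all(need %in% names(tb))) {
    abort_schema(paste0("label scheme file must have columns ",
                        paste(need, collapse = ", ")))
  }
  if (nrow(tb) == 0L) abort_schema("label scheme file has no rows")
  excl <- tb$original_label[tb$consolidated_label == EXCLUDE_SENTINEL]
  keep <- tb[tb$consolidated_label != EXCLUDE_SENTINEL, ]
  if (nrow(keep) == 0L) abort_schema("label scheme maps every label to EXCLUDE")
  label_scheme(setNames(keep$consolidated_label, keep$original_label), excluded = excl)
}

#' The packaged CATAMI-broad consolidation scheme
#'
#' Seven CATAMI-broad categories consolidated onto four classes:
#' unconsolidated substrate (`1_UnCon Sub`), macroalgae (`2_MA`), seagrass
#' (`3_SG`) and reef structure (`ReefStructure`, pooling sponge, hard coral,
#' soft coral and consolidated substrate).
#'
#' @return A [label_scheme()] with four classes.
#' @export
catami_scheme <- function() {
  load_label_scheme(system.file("extdata", "catami_consolidation.csv",
                                package = "benthoscan", mustWork = TRUE))
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme> ", length(x$mapping), " originals -> ",
      length(x$classes), " classes\n", sep = "")
  cat("classes: ", paste(x$classes, collapse = ", "), "\n", sep = "")
  if (length(x$excluded)) {
    cat("excluded: ", paste(x$excluded, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.label_scheme <- function(x, ...) {
  dplyr::bind_rows(
    tibble(original_label = names(x$mapping),
           consolidated_label = unname(x$mapping)),
    tibble(original_label = x$excluded,
           consolidated_label = rep(EXCLUDE_SENTINEL, length(x$excluded)))
  )
}

#' Consolidate annotation labels
#'
#' Rewrites the `label` column of an annotation table to consolidated class
#' names, dropping points whose original label is in the scheme's exclusion
#' set. Labels already equal to a consolidated class name pass through
#' unchanged. Row order of surviving points is preserved.
#'
#' @param ann Annotation tibble with at least columns `image_id` and `label`.
#' @param scheme A [label_scheme()].
#' @return The annotation tibble with consolidated labels.
#' @export
consolidate <- function(ann, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  if (!all(c("image_id", "label") %in% names(ann))) {
    abort_schema("annotation table must have columns image_id and label")
  }
  lab <- as.character(ann$label)
  known <- lab %in% names(scheme$mapping) | lab %in% scheme$classes | lab %in% scheme$excluded
  if (any(!known)) {
    i <- which(!known)[1]
    abort_schema(paste0("unknown label '", lab[i], "' (image_id '",
                        ann$image_id[i], "') not in scheme mapping, classes or exclusions"))
  }
  drop <- lab %in% scheme$excluded
  out <- ann[!drop, , drop = FALSE]
  lab <- lab[!drop]
  mapped <- lab %in% names(scheme$mapping)
  lab[mapped] <- unname(scheme$mapping[lab[mapped]])
  out$label <- lab
  as_tibble(out)
}
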