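# Point-annotation data model: the supervised unit is one image's 8 x 8 grid
# of labelled points. Coordinates are 0-based pixels, x = column, y = row,
# origin top-left.

#' Construct a source image record
#'
#' @param image_id Character id.
#' @param pixels H x W x 3 numeric array, intensities in \[0, 255\].
#' @param site_id,season_year Optional survey metadata.
#' @return A `source_image` object.
#' @export
source_image <- function(image_id, pixels, site_id = NA_character_,
                         season_year = NA_character_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort_schema("pixels must be an H x W x 3 array")
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) abort_schema("empty image")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) abort_schema("intensities must lie in [0, 255]")
  structure(list(image_id = as.character(image_id), pixels = pixels,
                 site_id = site_id, season_year = season_year),
            class = "source_image")
}

#' @export
print.source_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<source_image> ", x$image_id, ": ", d[2], "x", d[1], " px\n", sep = "")
  invisible(x)
}

as_pixels <- function(image) {
  if (inherits(image, "source_image")) return(image$pixels)
  if (is.character(image) && length(image) == 1L) return(read_image(image))
  if (is.array(image) && length(dim(image)) == 3L) return(image)
  abort_schema("image must be a source_image, an H x W x 3 array, or a file path")
}

#' Fixed 8 x 8 grid of annotation points for an image
#'
#' Partitions the image into an 8 x 8 grid of equal cells and places one
#' point at each cell centre: `x = floor((col + 0.5) * width / 8)`,
#' `y = floor((row + 0.5) * height / 8)`. The layout depends only on the
#' image dimensions, mirroring the fixed point template used in manual
#' point-count surveys.
#'
#' @param width,height Image dimensions in pixels; both must be at least 8.
#' @param n_grid Grid size per side (default 8, giving 64 points).
#' @return A tibble with columns `row`, `col` (0-based grid indices) and
#'   `x`, `y` (0-based pixel coordinates).
#' @export
grid_coordinates <- function(width, height, n_grid = 8L) {
  if (!is_count(width) || !is_count(height)) abort_config("width and height must be positive integers")
  if (width < n_grid || height < n_grid) {
    abort_degenerate(paste0("image dimensions (", width, "x", height,
                            ") are smaller than the ", n_grid, "-point grid"))
  }
  g <- tidyr::expand_grid(row = 0:(n_grid - 1L), col = 0:(n_grid - 1L))
  dplyr::mutate(g,
                x = as.integer(floor((.data$col + 0.5) * width / n_grid)),
                y = as.integer(floor((.data$row + 0.5) * height / n_grid)))
}

#' Survey area covered by a site's drop images
#'
#' Drop-video frames each cover a fixed seafloor footprint; a site's coverage
#' is the summed footprint of its frames (ten 0.2 m^2 drops give 2 m^2).
#'
#' @param n_images Number of drop images at the site.
#' @param footprint_m2 Seafloor area covered by one image, in m^2.
#' @return Total area in m^2.
#' @export
site_coverage <- function(n_images = 10, footprint_m2 = 0.2) {
  if (!is.numeric(n_images) || n_images < 0) abort_config("n_images must be non-negative")
  n_images * footprint_m2
}

#' Split image ids into training and testing sets
#'
#' The split unit is the image: all 64 points of an image land on the same
#' side, so no image leaks across the split. `floor(n * fraction)` ids go to
#' training. Identical `seed` gives an identical split.
#'
#' @param ids Character vector of image ids (at least 2, no duplicates).
#' @param fraction Training proportion, strictly between 0 and 1.
#' @param seed Integer seed controlling the random assignment.
#' @return A `split_assignment` with fields `train_ids`, `test_ids`,
#'   `fraction`, `seed`.
#' @export
split_by_image <- function(ids, fraction = 0.8, seed = 1L) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) abort_schema("duplicate image ids")
  if (length(ids) < 2L) abort_degenerate("need at least 2 ids to split")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort_config("fraction must be strictly between 0 and 1")
  }
  n_train <- max(1L, min(length(ids) - 1L, floor(length(ids) * fraction)))
  train <- local_seed(seed, sort(sample(ids, n_train)))
  structure(list(train_ids = train,
                 test_ids = sort(setdiff(ids, train)),
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("<split_assignment> ", length(x$train_ids), " train / ",
      length(x$test_ids), " test (fraction ", x$fraction,
      ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.split_assignment <- function(x, ...) {
  dplyr::bind_rows(tibble(image_id = x$train_ids, set = "train"),
                   tibble(image_id = x$test_ids, set = "test"))
}

ANNOTATION_COLS <- c("image_id", "row", "col", "x", "y", "label")

validate_annotations <- function(tb, image_dims = NULL) {
  miss <- setdiff(ANNOTATION_COLS, names(tb))
  if (length(miss)) {
    abort_schema(paste0("annotation table missing columns: ", paste(miss, collapse = ", ")))
  }
  num <- c("row", "col", "x", "y")
  for (cc in num) {
    if (any(is.na(tb[[cc]]))) {
      abort_schema(paste0("annotation row ", which(is.na(tb[[cc]]))[1],
                          ": missing value in column ", cc))
    }
  }
  if (any(tb$x < 0) || any(tb$y < 0)) {
    bad <- which(tb$x < 0 | tb$y < 0)[1]
    abort_schema(paste0("annotation row ", bad, ": negative pixel coordinate"))
  }
  dup <- duplicated(tb[, c("image_id", "row", "col")])
  if (any(dup)) {
    abort_schema(paste0("annotation row ", which(dup)[1],
                        ": duplicate (image_id, row, col)"))
  }
  if (!is.null(image_dims)) {
    j <- match(tb$image_id, image_dims$image_id)
    if (any(is.na(j))) {
      abort_schema(paste0("annotation row ", which(is.na(j))[1],
                          ": image_id not present in image_dims"))
    }
    oob <- tb$x >= image_dims$width[j] | tb$y >= image_dims$height[j]
    if (any(oob)) {
      bad <- which(oob)[1]
      abort_schema(paste0("annotation row ", bad, ": point (", tb$x[bad], ",",
                          tb$y[bad], ") outside image '", tb$image_id[bad], "' bounds"))
    }
  }
  invisible(tb)
}

#' Read a point-annotation CSV
#'
#' Expects the header `image_id,row,col,x,y,label`, one annotated point per
#' line. If `image_dims` (a tibble with `image_id`, `width`, `height`) is
#' given, every point is checked against its image bounds and the offending
#' row is named on failure.
#'
#' @param path Path to the CSV file.
#' @param image_dims Optional per-image dimensions for bounds checking.
#' @return A tibble of annotated points.
#' @export
read_annotations <- function(path, image_dims = NULL) {
  if (!file.exists(path)) abort_schema(paste0("annotation file not found: ", path))
  tb <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  miss <- setdiff(ANNOTATION_COLS, names(tb))
  if (length(miss)) {
    abort_schema(paste0("annotation table missing columns: ", paste(miss, collapse = ", ")))
  }
  for (cc in c("row", "col", "x", "y")) tb[[cc]] <- as.integer(tb[[cc]])
  validate_annotations(tb, image_dims)
  tb
}

#' Write a point-annotation CSV
#'
#' @param ann Annotation tibble (columns `image_id,row,col,x,y,label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  validate_annotations(ann)
  readr::write_csv(ann[, ANNOTATION_COLS], path, progress = FALSE)
  invisible(path)
}
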