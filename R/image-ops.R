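# Low-level raster operations. Images are H x W x 3 numeric arrays with
# intensities on [0, 255], x = column and y = row, both 0-based, origin at the
# top-left pixel. All operations are vectorized; no per-pixel R loops.

#' Read an RGB image from a PNG file
#'
#' @param path Path to a PNG file.
#' @return An H x W x 3 numeric array with intensities in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort_schema(paste0("image file not found: ", path))
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px * 255
}

#' Write an RGB image to a PNG file
#'
#' @param pixels H x W x 3 numeric array, intensities in \[0, 255\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  px <- clamp01(pixels / 255)
  png::writePNG(px, path)
  invisible(path)
}

# Write a class-index mask (integer matrix, values 0..n-1) as an 8-bit
# grayscale PNG holding the raw index; read back with read_mask().
write_mask <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear sample of a single-channel matrix at fractional (row, col)
# positions (1-based, matrix convention); coordinates are clamped to the
# valid domain so edges replicate.
bilinear_sample <- function(m, ri, ci) {
  H <- nrow(m); W <- ncol(m)
  ri <- clamp(ri, 1, H); ci <- clamp(ci, 1, W)
  r0 <- pmin(floor(ri), H - 1L); c0 <- pmin(floor(ci), W - 1L)
  fr <- ri - r0; fc <- ci - c0
  i00 <- r0 + (c0 - 1) * H
  v <- m[i00] * (1 - fr) * (1 - fc) + m[i00 + 1] * fr * (1 - fc) +
    m[i00 + H] * (1 - fr) * fc + m[i00 + H + 1] * fr * fc
  v
}

# Dense 1-D bilinear interpolation weights (n_out x n_in), centre-aligned
# with edge replication; a 2-D bilinear resize is two such products.
interp_weights <- function(n_out, n_in) {
  if (n_in == 1L) return(matrix(1, n_out, 1L))
  ri <- clamp((seq_len(n_out) - 0.5) * n_in / n_out + 0.5, 1, n_in)
  r0 <- pmin(floor(ri), n_in - 1L)
  fr <- ri - r0
  w <- matrix(0, n_out, n_in)
  w[cbind(seq_len(n_out), r0)] <- 1 - fr
  w[cbind(seq_len(n_out), r0 + 1L)] <- w[cbind(seq_len(n_out), r0 + 1L)] + fr
  w
}

#' Resize an image with bilinear interpolation
#'
#' Separable (row, then column) bilinear resampling, centre-aligned, with
#' edge replication.
#'
#' @param pixels H x W x C numeric array (or a matrix).
#' @param width,height Output dimensions in pixels.
#' @return Resized array of shape `height` x `width` x C.
#' @export
resize_image <- function(pixels, width, height) {
  if (!is_count(width) || !is_count(height)) abort_config("width and height must be positive integers")
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  H <- dim(pixels)[1]; W <- dim(pixels)[2]; C <- dim(pixels)[3]
  wr <- interp_weights(height, H)
  wc <- t(interp_weights(width, W))
  out <- array(0, c(height, width, C))
  for (k in seq_len(C)) out[, , k] <- wr %*% pixels[, , k] %*% wc
  if (C == 1L) out[, , 1] else out
}

# Rotate an image about its centre by `angle` degrees (counter-clockwise in
# the x-right / y-down raster frame), keeping the canvas size; out-of-frame
# samples replicate the nearest edge pixel.
rotate_image <- function(pixels, angle) {
  th <- angle * pi / 180
  H <- dim(pixels)[1]; W <- dim(pixels)[2]; C <- dim(pixels)[3]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rim0 <- matrix(seq_len(H), H, W) - cy
  cim0 <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse rotation of the output grid
  ci <- cos(th) * cim0 + sin(th) * rim0 + cx
  ri <- -sin(th) * cim0 + cos(th) * rim0 + cy
  out <- array(0, dim(pixels))
  for (k in seq_len(C)) out[, , k] <- bilinear_sample(pixels[, , k], ri, ci)
  out
}

# Forward-rotate 0-based point coordinates to match rotate_image().
rotate_points <- function(x, y, width, height, angle) {
  th <- angle * pi / 180
  cx <- (width - 1) / 2; cy <- (height - 1) / 2
  dx <- x - cx; dy <- y - cy
  list(x = cos(th) * dx - sin(th) * dy + cx,
       y = sin(th) * dx + cos(th) * dy + cy)
}

# Smooth random field: coarse iid normals bilinearly upsampled to H x W.
# `scale` is the approximate correlation length in pixels; distinct
# `scale_x` / `scale_y` give anisotropic (elongated) structure.
smooth_noise <- function(height, width, scale, sd = 1,
                         scale_y = scale, scale_x = scale) {
  nh <- max(2L, ceiling(height / scale_y) + 1L)
  nw <- max(2L, ceiling(width / scale_x) + 1L)
  coarse <- matrix(rnorm(nh * nw, sd = sd), nh, nw)
  resize_image(coarse, width, height)
}

# Nearest-neighbour upsampled noise: blocky, high-contrast.
blocky_noise <- function(height, width, block, sd = 1) {
  nh <- ceiling(height / block); nw <- ceiling(width / block)
  coarse <- matrix(rnorm(nh * nw, sd = sd), nh, nw)
  coarse[rep(seq_len(nh), each = block)[seq_len(height)],
         rep(seq_len(nw), each = block)[seq_len(width)]]
}
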