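#' Single-channel fluorescence image
#'
#' A thin wrapper around a numeric matrix of photon-scaled intensities with
#' the physical pixel size and a channel label attached. Rows are image rows
#' (y), columns are image columns (x); pixel centers sit at integer 1-based
#' coordinates.
#'
#' @param intensities numeric matrix, non-negative and finite, at least
#'   16 x 16.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param channel channel label, e.g. `"p120ctn"` or `"DAPI"`.
#' @return A `fluor_image` object (a matrix with attributes).
#' @examples
#' img <- fluor_image(matrix(1, 32, 32), pixel_size = 0.2, channel = "marker")
#' dim(img)
#' @export
fluor_image <- function(intensities, pixel_size = 1, channel = "marker") {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    abort("`intensities` must be a numeric matrix.")
  }
  if (nrow(intensities) < 16 || ncol(intensities) < 16) {
    abort("image must be at least 16 x 16 pixels.")
  }
  if (any(!is.finite(intensities))) abort("image intensities must be finite.")
  if (any(intensities < 0)) abort("image intensities must be non-negative.")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number (um/pixel).")
  }
  structure(intensities,
    pixel_size = pixel_size, channel = as.character(channel),
    class = c("fluor_image", "matrix", "array")
  )
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf(
    "<fluor_image> %d x %d px, %.3g um/px, channel '%s'\n",
    nrow(x), ncol(x), attr(x, "pixel_size"), attr(x, "channel")
  ))
  cat(sprintf(
    "  intensity range [%.3g, %.3g]\n", min(x), max(x)
  ))
  invisible(x)
}

#' @rdname fluor_image
#' @param x object to test or print.
#' @export
is_fluor_image <- function(x) inherits(x, "fluor_image")

#' Pixel size accessor
#' @param image a [fluor_image()].
#' @return pixel size in um/pixel.
#' @export
pixel_size <- function(image) {
  ps <- attr(image, "pixel_size")
  if (is.null(ps)) 1 else ps
}

# Bilinear interpolation at arbitrary (row, col) positions.
# Never extrapolates: any query outside [1, nrow] x [1, ncol] is an error.
bilinear_at <- function(mat, row, col) {
  nr <- nrow(mat); nc <- ncol(mat)
  bad <- row < 1 | row > nr | col < 1 | col > nc
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "sample position (row = %.2f, col = %.2f) falls outside the image (%d x %d).",
      row[i], col[i], nr, nc
    ))
  }
  r0 <- pmin(floor(row), nr - 1); c0 <- pmin(floor(col), nc - 1)
  fr <- row - r0; fc <- col - c0
  v00 <- mat[cbind(r0, c0)];     v01 <- mat[cbind(r0, c0 + 1)]
  v10 <- mat[cbind(r0 + 1, c0)]; v11 <- mat[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

#' Maximum-intensity projection of an image stack
#'
#' Confocal acquisitions taken as z-stacks (e.g. ten focal planes per field)
#' are reduced to a single 2D image before profile extraction or blob
#' detection; the per-pixel maximum over planes is used.
#'
#' @param stack a list of numeric matrices with identical dimensions, or a
#'   3D array with planes along the third dimension.
#' @inheritParams fluor_image
#' @return A [fluor_image()] holding the per-pixel maximum.
#' @export
max_intensity_projection <- function(stack, pixel_size = 1, channel = "marker") {
  if (is.array(stack) && length(dim(stack)) == 3) {
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  }
  if (!is.list(stack) || length(stack) == 0) {
    abort("`stack` must be a non-empty list of matrices or a 3D array.")
  }
  dims <- unique(lapply(stack, dim))
  if (length(dims) != 1) abort("all planes must share the same dimensions.")
  proj <- Reduce(pmax, stack)
  fluor_image(proj, pixel_size = pixel_size, channel = channel)
}

#' Read / write single-channel TIFF images
#'
#' Convenience I/O for instrument exports. Intensities are stored as 16-bit
#' (values scaled to the 0..65535 range on write and restored on read when a
#' scale is given). Requires the `tiff` package.
#'
#' @param path file path.
#' @param pixel_size,channel metadata attached to the returned image.
#' @param scale maximum photon count that maps to the top of the 16-bit
#'   range; use the same value when writing and reading.
#' @return `read_image_tiff()` returns a [fluor_image()];
#'   `write_image_tiff()` returns `path` invisibly.
#' @export
read_image_tiff <- function(path, pixel_size = 1, channel = "marker",
                            scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required for TIFF I/O.")
  }
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  fluor_image(m * scale, pixel_size = pixel_size, channel = channel)
}

#' @rdname read_image_tiff
#' @param image a [fluor_image()].
#' @export
write_image_tiff <- function(image, path, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required for TIFF I/O.")
  }
  m <- unclass(image)
  attributes(m) <- list(dim = dim(m))
  tiff::writeTIFF(pmin(m / scale, 1), path, bits.per.sample = 16L)
  invisible(path)
}
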