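#' Grayscale image with pixel-density metadata
#'
#' Wraps a numeric matrix as a `gray_image`, optionally carrying the pixel
#' density (pixels per millimetre) that converts digital frequencies to
#' cycles/mm.  All package functions accept either plain matrices or
#' `gray_image` objects; metadata is preserved where it makes sense.
#'
#' @param pixels numeric matrix of intensities (nominal range 0-255, but any
#'   finite values are accepted).
#' @param pixel_density pixels per mm, or `NULL` if unknown.
#' @return a `gray_image` object (a numeric matrix with attributes).
#' @examples
#' img <- gray_image(matrix(runif(64, 0, 255), 8, 8), pixel_density = 16.66)
#' pixel_density(img)
#' @export
gray_image <- function(pixels, pixel_density = NULL) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("'pixels' must be a numeric matrix")
  if (!all(is.finite(pixels))) stop("image contains non-finite values")
  storage.mode(pixels) <- "double"
  if (!is.null(pixel_density)) {
    if (!is.numeric(pixel_density) || length(pixel_density) != 1L || pixel_density <= 0)
      stop("'pixel_density' must be a single positive number")
    attr(pixels, "pixel_density") <- as.numeric(pixel_density)
  }
  class(pixels) <- c("gray_image", class(pixels))
  pixels
}

#' @rdname gray_image
#' @param x a `gray_image` or matrix.
#' @export
pixel_density <- function(x) attr(x, "pixel_density")

#' @export
print.gray_image <- function(x, ...) {
  pd <- pixel_density(x)
  cat(sprintf("gray_image: %d x %d pixels, range [%.4g, %.4g]%s\n",
              nrow(x), ncol(x), min(x), max(x),
              if (is.null(pd)) "" else sprintf(", %.4g px/mm", pd)))
  invisible(x)
}

#' @export
plot.gray_image <- function(x, ..., main = NULL) {
  m <- unclass(x)
  # display with row 1 at the top, as stored
  image(t(m[nrow(m):1, , drop = FALSE]), col = gray.colors(256), axes = FALSE,
        asp = nrow(m) / ncol(m), main = main, ...)
  invisible(x)
}

# strip class/attrs, keep plain double matrix
as_pixel_matrix <- function(x) {
  m <- unclass(as.matrix(x))
  attr(m, "pixel_density") <- NULL
  storage.mode(m) <- "double"
  m
}

# rebuild an output image carrying over metadata from the input
restore_image <- function(pixels, template) {
  if (inherits(template, "gray_image"))
    gray_image(pixels, pixel_density = pixel_density(template))
  else pixels
}

# Symmetric (half-sample) reflection of 1-based indices into 1..n:
# ... 2 1 | 1 2 ... n | n n-1 ...  Shared by every windowed operation and
# finite-difference stencil in the package (and by the test oracles).
reflect_index <- function(i, n) {
  k <- (i - 1L) %% (2L * n)
  ifelse(k < n, k, 2L * n - 1L - k) + 1L
}

# Shift a matrix by (dr, dc) with reflected boundaries: result[i,j] = m[i+dr, j+dc]
shift_reflect <- function(m, dr = 0L, dc = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- reflect_index(seq_len(nr) + dr, nr)
  ci <- reflect_index(seq_len(nc) + dc, nc)
  m[ri, ci, drop = FALSE]
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Separable convolution with reflected boundaries (kernel assumed odd-length)
convolve_sep <- function(m, kernel) {
  r <- (length(kernel) - 1L) / 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (o in seq_along(kernel)) out <- out + kernel[o] * shift_reflect(m, dr = o - r - 1L)
  res <- matrix(0, nrow(m), ncol(m))
  for (o in seq_along(kernel)) res <- res + kernel[o] * shift_reflect(out, dc = o - r - 1L)
  res
}

#' Read and write grayscale images
#'
#' Thin wrappers over the `tiff` and `png` packages used by the command-line
#' front end.  16-bit/float TIFF and 8-bit PNG are supported; intensities are
#' rescaled to the nominal 0-255 range on read when the file stores 0-1.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param pixel_density pixels per mm to attach to the result (optional).
#' @return `read_gray_image()` returns a [gray_image()].
#' @export
read_gray_image <- function(path, pixel_density = NULL) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' is required")
      tiff::readTIFF(path)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' is required")
      png::readPNG(path)
    },
    stop("unsupported image format: ", ext))
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  if (max(m) <= 1) m <- m * 255
  gray_image(m, pixel_density = pixel_density)
}

#' @rdname read_gray_image
#' @param image matrix or [gray_image()] to write.
#' @details TIFF output is 16-bit, min-max scaled to the sample range; the
#'   range used is returned invisibly (and recorded in the command-line
#'   front end's parameter sidecar) so rasters in physical units can be
#'   reconstructed.
#' @export
write_gray_image <- function(image, path) {
  m <- as_pixel_matrix(image)
  ext <- tolower(tools::file_ext(path))
  rng <- range(m)
  switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' is required")
      scaled <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else pmin(pmax(m, 0), 1)
      tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' is required")
      png::writePNG(pmin(pmax(m / 255, 0), 1), path)
    },
    stop("unsupported image format: ", ext))
  invisible(rng)
}
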