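#' Standardize image resolution
#'
#' Resamples an image to the reference pixel density (16.66 px/mm) with
#' separable cubic-spline interpolation, so that digital frequencies map to
#' the same continuous-space frequencies across a cohort.  Interpolation
#' adds no information: high-frequency content is only comparable to the
#' extent it was present at acquisition.
#'
#' @param image matrix or [gray_image()]; its pixel density must be known
#'   (attribute or `current_density`).
#' @param target_density target pixels per mm.
#' @param current_density source pixels per mm (overrides the attribute).
#' @return the resampled [gray_image()] at `target_density`.
#' @examples
#' img <- gray_image(matrix(runif(100 * 100), 100, 100), pixel_density = 8.33)
#' dim(standardize_resolution(img))  # 200 x 200
#' @export
standardize_resolution <- function(image, target_density = 16.66,
                                   current_density = NULL) {
  pd <- current_density %||% pixel_density(image)
  if (is.null(pd) || !is.finite(pd) || pd <= 0)
    stop("pixel density of the input is unknown; supply 'current_density'")
  m <- as_pixel_matrix(image)
  f <- target_density / pd
  if (abs(f - 1) < 1e-9)
    return(gray_image(m, pixel_density = target_density))
  newH <- max(2L, round(nrow(m) * f))
  newW <- max(2L, round(ncol(m) * f))
  # separable cubic spline: columns then rows (edge-aligned sampling grid)
  xout <- seq(1, ncol(m), length.out = newW)
  tmp <- t(apply(m, 1, function(row) spline(seq_along(row), row, xout = xout)$y))
  yout <- seq(1, nrow(m), length.out = newH)
  out <- apply(tmp, 2, function(col) spline(seq_along(col), col, xout = yout)$y)
  gray_image(matrix(out, newH, newW), pixel_density = target_density)
}

#' Normalize image intensity against blood and adventitia references
#'
#' Linearly rescales gray levels so that the median of a user-selected blood
#' region maps to 2.5 and the median of an adventitia (artery wall) region
#' maps to 185 (midpoints of the conventional 0-5 and 180-190 target
#' ranges), then clips to `[0, 255]`.  The map is affine, so intensity
#' orderings are preserved up to clipping.
#'
#' @param image matrix or [gray_image()].
#' @param blood_median,adventitia_median reference gray levels measured on
#'   the input; the adventitia value must exceed the blood value.
#' @param targets length-2 target gray levels for blood and adventitia.
#' @param clip length-2 output clipping range.
#' @return the normalized image, same type as the input.
#' @examples
#' img <- matrix(c(30, 115, 200), 3, 3)
#' normalize_intensity(img, blood_median = 30, adventitia_median = 200)[, 1]
#' @export
normalize_intensity <- function(image, blood_median, adventitia_median,
                                targets = c(2.5, 185), clip = c(0, 255)) {
  if (adventitia_median <= blood_median)
    stop("'adventitia_median' must exceed 'blood_median'")
  m <- as_pixel_matrix(image)
  slope <- diff(targets) / (adventitia_median - blood_median)
  out <- targets[1] + slope * (m - blood_median)
  out <- pmin(pmax(out, clip[1]), clip[2])
  restore_image(out, image)
}

#' Extract a fixed-length region of interest from a segmentation mask
#'
#' Restricts a segmentation mask (e.g. the intima-media complex band between
#' the lumen-intima and media-adventitia interfaces) to a window of
#' `length` columns (160 px = 9.6 mm at 16.66 px/mm) centred at the mask's
#' column centroid, so that measurements are comparable across images.
#'
#' @param mask logical matrix.
#' @param length window length in columns (pixels).
#' @return the mask with columns outside the window set to `FALSE`.
#' @export
extract_roi <- function(mask, length = 160L) {
  mask <- mask != 0
  cols <- which(colSums(mask) > 0)
  if (!base::length(cols)) stop("mask is empty")
  extent <- max(cols) - min(cols) + 1L
  if (extent < length)
    stop("mask horizontal extent (", extent, " columns) is smaller than the ",
         length, "-column window")
  # centroid = mean column of mask pixels, ties rounded down
  centroid <- ceiling(mean(rep(cols, colSums(mask)[cols])) - 0.5)
  first <- centroid - length %/% 2L            # window = centroid-80 .. centroid+79
  # keep the window over mask support (and inside the image) when it
  # protrudes; extent >= length guarantees this is feasible
  first <- min(max(first, min(cols)), max(cols) - length + 1L)
  first <- min(max(first, 1L), ncol(mask) - length + 1L)
  keep <- first:(first + length - 1L)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[, keep] <- mask[, keep]
  out
}
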