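#' Specify a synthetic AM-FM carotid phantom
#'
#' The phantom is a piecewise-banded chirp image that mimics a longitudinal
#' B-mode view of the common carotid artery: wide "background" bands of
#' moderate amplitude play the role of tissue, and two narrow bright strips
#' play the role of the intima-media complex walls.  Each horizontal band has
#' a constant amplitude `A` and an instantaneous frequency along rows (the
#' `x` axis) that sweeps linearly across columns from `ifx_min` to `ifx_max`;
#' the column-direction frequency is `ify_sign * ifx`.
#'
#' @param height,width image size in pixels.
#' @param bands data frame with columns `row_start`, `row_end` (0-based,
#'   inclusive), `amplitude`, `ifx_min`, `ifx_max` (rad/pixel, in `(0, pi)`)
#'   and `ify_sign` (+1 or -1).  Bands must partition `0:(height-1)`.
#' @param sweep_axis axis along which the row-frequency sweeps; only
#'   `"columns"` (constant frequency per column) is implemented.
#' @return a `phantom_spec` object.
#' @seealso [carotid_phantom_spec()] for the default five-band phantom,
#'   [generate_phantom()] to realize it.
#' @export
phantom_spec <- function(height = 1024L, width = 1024L, bands,
                         sweep_axis = c("columns")) {
  sweep_axis <- match.arg(sweep_axis)
  bands <- as.data.frame(bands)
  need <- c("row_start", "row_end", "amplitude", "ifx_min", "ifx_max", "ify_sign")
  if (!all(need %in% names(bands)))
    stop("'bands' must have columns: ", paste(need, collapse = ", "))
  bands <- bands[order(bands$row_start), , drop = FALSE]
  if (bands$row_start[1] != 0L || bands$row_end[nrow(bands)] != height - 1L ||
      (nrow(bands) > 1L && any(bands$row_start[-1] != bands$row_end[-nrow(bands)] + 1L)))
    stop("bands must partition rows 0..height-1 with no gap or overlap")
  if (any(bands$ifx_min > bands$ifx_max) ||
      any(bands$ifx_min <= 0) || any(bands$ifx_max >= pi))
    stop("band frequencies must satisfy 0 < ifx_min <= ifx_max < pi")
  if (!all(bands$ify_sign %in% c(-1, 1)))
    stop("ify_sign must be +1 or -1")
  structure(list(height = as.integer(height), width = as.integer(width),
                 bands = bands, sweep_axis = sweep_axis),
            class = "phantom_spec")
}

#' Default five-band carotid phantom specification
#'
#' A 1024 x 1024 phantom with three "background" bands (amplitudes 158, 102
#' and 182; row frequency sweeping over `[pi/7.5, pi/4.5]` rad/pixel with
#' `ify = -ifx`) and two narrow bright strips (amplitude 250, rows 273-306
#' and 703-750; frequency over `[pi/6.5, pi/5.5]` with `ify = +ifx`).
#'
#' @param height,width image size in pixels; for heights other than 1024 the
#'   five band boundaries are scaled proportionally (useful for quick
#'   small-scale runs).
#' @return a [phantom_spec()].
#' @export
carotid_phantom_spec <- function(height = 1024L, width = 1024L) {
  bg <- c(pi / 7.5, pi / 4.5)
  st <- c(pi / 6.5, pi / 5.5)
  starts <- c(0L, 273L, 307L, 703L, 751L)
  if (height != 1024L) {
    starts <- as.integer(round(starts * height / 1024))
    starts[1] <- 0L
    if (any(diff(starts) < 1L)) stop("height too small for the five-band layout")
  }
  ends <- c(starts[-1] - 1L, as.integer(height) - 1L)
  bands <- data.frame(
    row_start = starts,
    row_end   = ends,
    amplitude = c(158, 250, 102, 250, 182),
    ifx_min   = c(bg[1], st[1], bg[1], st[1], bg[1]),
    ifx_max   = c(bg[2], st[2], bg[2], st[2], bg[2]),
    ify_sign  = c(-1, 1, -1, 1, -1),
    role      = c("background", "strip", "background", "strip", "background"),
    stringsAsFactors = FALSE
  )
  phantom_spec(height = height, width = width, bands = bands)
}

#' Generate a phantom image with ground truth
#'
#' Realizes a [phantom_spec()] as `f(x, y) = A(x) * cos(phi(x, y))` with
#' `phi(x, y) = omega(y) * (x + s * y)` inside each band, where `omega(y)`
#' sweeps linearly across columns between the band's frequency limits and
#' `s` is the band's `ify_sign`.  The row-direction discrete derivative of
#' the phase is exactly `omega(y)`; the column-direction derivative equals
#' `s * omega(y)` up to a slow chirp term (the deliberate model mismatch
#' that makes the y-frequency harder to estimate than the x-frequency, as in
#' real sweeps).
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_truth` object: list with `image` (the noise-free
#'   [gray_image()]), `ia_true`, `ifx_true`, `ify_true` rasters (rad/pixel,
#'   signed), and `masks` (`backgrounds`, `strips`, `combined` logical
#'   rasters).  Strips are the bands with `ify_sign == +1` (or flagged by a
#'   `role` column when present).
#' @examples
#' tr <- generate_phantom(carotid_phantom_spec(height = 64L, width = 64L))
#' @export
generate_phantom <- function(spec = carotid_phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height; W <- spec$width
  ycol <- seq_len(W) - 1
  img <- matrix(0, H, W)
  ia <- matrix(0, H, W)
  ifx <- matrix(0, H, W)
  ify <- matrix(0, H, W)
  strip_mask <- matrix(FALSE, H, W)
  b <- spec$bands
  roles <- if ("role" %in% names(b)) b$role else ifelse(b$ify_sign > 0, "strip", "background")
  for (k in seq_len(nrow(b))) {
    rows <- (b$row_start[k]:b$row_end[k]) + 1L
    rows <- rows[rows >= 1L & rows <= H]
    if (!length(rows)) next
    omega <- if (W > 1L)
      b$ifx_min[k] + (b$ifx_max[k] - b$ifx_min[k]) * ycol / (W - 1)
    else rep(b$ifx_min[k], W)
    s <- b$ify_sign[k]
    xr <- rows - 1  # 0-based row coordinate
    # phase phi(x, y) = omega(y) * (x + s*y)
    phase <- outer(xr, omega) + matrix(s * omega * ycol, length(rows), W, byrow = TRUE)
    img[rows, ] <- b$amplitude[k] * cos(phase)
    ia[rows, ] <- b$amplitude[k]
    ifx[rows, ] <- matrix(omega, length(rows), W, byrow = TRUE)
    ify[rows, ] <- matrix(s * omega, length(rows), W, byrow = TRUE)
    if (roles[k] == "strip") strip_mask[rows, ] <- TRUE
  }
  structure(list(
    image = gray_image(img, pixel_density = 16.66),
    ia_true = ia, ifx_true = ifx, ify_true = ify,
    masks = list(backgrounds = !strip_mask, strips = strip_mask,
                 combined = matrix(TRUE, H, W)),
    spec = spec), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %d x %d, %d bands (%d strip rows)\n",
              nrow(x$image), ncol(x$image), nrow(x$spec$bands), sum(x$masks$strips[, 1])))
  invisible(x)
}

#' @export
plot.phantom_truth <- function(x, ...) plot(x$image, main = "phantom", ...)

#' Multiplicative speckle specification
#'
#' Zero-mean uniform multiplicative noise: `g = f + n * f` with
#' `n ~ Uniform(-a, a)` i.i.d. and `a = sqrt(3 * variance)`.
#'
#' @param variance noise variance (dimensionless; 0.07 emulates moderately
#'   speckled B-mode tissue).
#' @param seed integer RNG seed making realizations reproducible.
#' @return a `speckle_spec` object.
#' @export
speckle_spec <- function(variance = 0.07, seed = 0L) {
  if (!is.numeric(variance) || length(variance) != 1L || variance < 0)
    stop("'variance' must be a single nonnegative number")
  structure(list(distribution = "uniform", variance = as.numeric(variance),
                 mean = 0, seed = as.integer(seed)), class = "speckle_spec")
}

#' Corrupt an image with multiplicative speckle
#'
#' @param truth a `phantom_truth` (its `image` is used) or any image matrix.
#' @param noise a [speckle_spec()].
#' @return the noisy [gray_image()] `g = f + n * f`.
#' @examples
#' tr <- generate_phantom(carotid_phantom_spec(height = 64L, width = 64L))
#' g <- add_speckle(tr, speckle_spec(variance = 0.07, seed = 1L))
#' @export
add_speckle <- function(truth, noise = speckle_spec()) {
  stopifnot(inherits(noise, "speckle_spec"))
  img <- if (inherits(truth, "phantom_truth")) truth$image else truth
  f <- as_pixel_matrix(img)
  if (noise$variance == 0) return(restore_image(f, img))
  a <- sqrt(3 * noise$variance)
  n <- with_local_seed(noise$seed, runif(length(f), min = -a, max = a))
  restore_image(f + n * f, img)
}

# Evaluate expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
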