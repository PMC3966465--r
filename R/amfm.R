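#' Dyadic frequency scales for multiscale AM-FM analysis
#'
#' The three dyadic magnitude bands used for carotid texture analysis, in
#' cycles/mm at the reference pixel density of 16.66 px/mm:
#' low 1.04-2.95 (instantaneous wavelengths 5.66-16 px), medium 2.08-5.89
#' (2.83-8 px) and high 4.17-11.79 cycles/mm (1.41-4 px).  Each band carries
#' the set of pixel spacings `n_set` its variable-spacing IF estimator may
#' use: `{1,2,3,4}` for low, `{1,2}` for medium, `{1}` for high.
#'
#' @param which character subset of `c("low", "medium", "high")`.
#' @return a named list of scale-band descriptors (`name`, `f_min`, `f_max`
#'   in cycles/mm, `iw_min`, `iw_max` in pixels, `n_set`).
#' @export
scale_bands <- function(which = c("low", "medium", "high")) {
  all <- list(
    low    = list(name = "low",    f_min = 1.04, f_max = 2.95,
                  iw_min = 5.66, iw_max = 16,  n_set = 1:4),
    medium = list(name = "medium", f_min = 2.08, f_max = 5.89,
                  iw_min = 2.83, iw_max = 8,   n_set = 1:2),
    high   = list(name = "high",   f_min = 4.17, f_max = 11.79,
                  iw_min = 1.41, iw_max = 4,   n_set = 1L)
  )
  which <- match.arg(which, several.ok = TRUE)
  all[which]
}

# Signed FFT frequencies in cycles/sample; the Nyquist bin (even n) is
# mapped to +1/2 so it belongs to the retained half-plane.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) / n
  f
}

#' Analytic (extended 2D Hilbert) image
#'
#' Builds the complex-valued image whose one-sided spectrum defines IA and
#' IF: the 2D FFT is taken, the two quadrants with negative column frequency
#' are zeroed, the two retained quadrants are doubled, and the DC and Nyquist
#' columns are kept with weight 1, so that the real part reproduces the input
#' exactly and a pure column tone `cos(w*y)` maps to `exp(i*w*y)`.
#'
#' @param image matrix or [gray_image()].
#' @return a complex matrix of the same size.
#' @examples
#' a <- analytic_image(matrix(cos(0.5 * (0:63)), 16, 64, byrow = TRUE))
#' max(abs(Mod(a) - 1)) # constant modulus for an in-band tone
#' @export
analytic_image <- function(image) {
  m <- as_pixel_matrix(image)
  H <- nrow(m); W <- ncol(m)
  Fm <- fft(m)
  k <- 0:(W - 1)
  w <- numeric(W)
  w[k == 0] <- 1
  if (W %% 2 == 0) w[k == W / 2] <- 1
  w[k > 0 & k < W / 2] <- 2
  Fa <- Fm * matrix(w, H, W, byrow = TRUE)
  fft(Fa, inverse = TRUE) / (H * W)
}

taper_profile <- function(x, flat, edge) {
  w <- numeric(length(x))
  w[x <= flat] <- 1
  tr <- x > flat & x < edge
  w[tr] <- cos((pi / 2) * (x[tr] - flat) / (edge - flat))^2
  w
}

#' Build a frequency-domain channel filterbank for one or more scales
#'
#' Channels are raised-cosine flat-top annular sectors over the retained
#' (nonnegative column frequency) half-plane.  Radially each channel is flat
#' across its scale's magnitude band (converted from cycles/mm to
#' cycles/pixel via the pixel density) with cosine tails extending
#' `radial_taper` relative width outside it; angularly the half-plane is
#' covered by `n_orient` sectors centred at 0, 45, 90 and 135 degrees (flat
#' within `flat_deg`, cosine rolloff to `edge_deg`, the 0-degree sector
#' wrapping to 180).  Centres are chosen so axis-aligned and diagonal tones
#' sit in flat regions.
#'
#' @param dim image dimensions `c(rows, cols)`.
#' @param pixel_density pixels per mm.
#' @param bands list of scale bands from [scale_bands()].
#' @param n_orient orientation sectors per scale.
#' @param flat_deg,edge_deg angular flat half-width and edge half-width, deg.
#' @param radial_taper relative width of the radial cosine tails.
#' @return named list (per scale) of lists of real transfer-function
#'   matrices in FFT layout.
#' @export
build_filterbank <- function(dim, pixel_density = 16.66, bands = scale_bands(),
                             n_orient = 4L, flat_deg = 15, edge_deg = 30,
                             radial_taper = 0.15) {
  if (pixel_density <= 0) stop("'pixel_density' must be > 0")
  H <- dim[1]; W <- dim[2]
  u <- fft_freq(H)  # row frequency, cycles/px
  v <- fft_freq(W)  # column frequency, cycles/px
  U <- matrix(u, H, W)
  V <- matrix(v, H, W, byrow = TRUE)
  r <- sqrt(U^2 + V^2)
  theta <- atan2(V, U) * 180 / pi   # in [0, 180] where V >= 0
  centers <- (seq_len(n_orient) - 1L) * 180 / n_orient
  out <- list()
  for (b in bands) {
    f1 <- b$f_min / pixel_density
    f2 <- b$f_max / pixel_density
    if (f1 >= sqrt(2) / 2)
      stop(sprintf("band '%s' (%.3g cycles/px) exceeds the 2D Nyquist at %.4g px/mm",
                   b$name, f1, pixel_density))
    lo <- f1 * (1 - radial_taper); hi <- f2 * (1 + radial_taper)
    rad <- matrix(0, H, W)
    rad[r >= f1 & r <= f2] <- 1
    rise <- r > lo & r < f1
    rad[rise] <- cos((pi / 2) * (f1 - r[rise]) / (f1 - lo))^2
    fall <- r > f2 & r < hi
    rad[fall] <- cos((pi / 2) * (r[fall] - f2) / (hi - f2))^2
    chans <- vector("list", n_orient)
    for (ci in seq_len(n_orient)) {
      d <- abs(theta - centers[ci]) %% 180
      d <- pmin(d, 180 - d)
      mask <- rad * taper_profile(d, flat_deg, edge_deg)
      mask[V < 0] <- 0
      chans[[ci]] <- mask
    }
    out[[b$name]] <- chans
  }
  out
}

#' Dominant-component selection over a scale's channels
#'
#' Filters the analytic image through each channel of one scale and, pixel
#' by pixel, keeps the channel with maximum response modulus: the IA is that
#' modulus and the phase is the argument of the winning response.  Modulus
#' ties keep the lowest channel index.
#'
#' @param analytic complex matrix from [analytic_image()].
#' @param masks list of channel transfer functions for one scale (an element
#'   of [build_filterbank()]'s result).
#' @return list with `ia`, `phase` and `channel_index` matrices.
#' @export
dominant_component <- function(analytic, masks) {
  H <- nrow(analytic); W <- ncol(analytic)
  Fa <- fft(analytic)
  ia <- matrix(-Inf, H, W)
  phase <- matrix(0, H, W)
  idx <- matrix(NA_integer_, H, W)
  for (ci in seq_along(masks)) {
    resp <- fft(Fa * masks[[ci]], inverse = TRUE) / (H * W)
    m <- Mod(resp)
    upd <- m > ia
    ia[upd] <- m[upd]
    phase[upd] <- Arg(resp)[upd]
    idx[upd] <- ci
  }
  list(ia = ia, phase = phase, channel_index = idx)
}

#' Variable-spacing instantaneous-frequency estimation
#'
#' Estimates the IF components from the unit-amplitude FM image
#' `fm = cos(phase)` using, for each allowed spacing `n`,
#' `arg_n = (fm(x+n, y) + fm(x-n, y)) / (2 * fm(x, y))` and
#' `ifx = arccos(arg_n) / n` (and likewise along columns for `ify`).  Among
#' spacings with `|arg_n| <= 1` the one with the minimum `|arg_n|` is kept
#' (most accurate; ties keep the smallest spacing).  Pixels where `|fm|`
#' falls below `floor` or where no spacing is admissible are flagged
#' invalid.  The estimator is exact on cosines and returns unsigned
#' frequencies in `[0, pi]` rad/pixel.
#'
#' @param fm matrix, the estimated FM image `cos(phase)`.
#' @param n_set integer spacings to consider (e.g. `1:4` at the low scale).
#' @param floor smallest usable `|fm|` at the centre pixel.
#' @return list with `ifx`, `ify` (rad/pixel, `NA` where invalid) and the
#'   logical `valid` raster.
#' @examples
#' fm <- matrix(cos(0.4 * (0:31)), 32, 32)        # tone along rows
#' est <- estimate_if(fm, n_set = 1:4)
#' range(est$ifx[est$valid])                      # 0.4 exactly
#' @export
estimate_if <- function(fm, n_set = 1:4, floor = 1e-3) {
  fm <- as_pixel_matrix(fm)
  den_ok <- abs(fm) >= floor
  one_dir <- function(dr, dc) {
    best_abs <- matrix(Inf, nrow(fm), ncol(fm))
    best_arg <- matrix(NA_real_, nrow(fm), ncol(fm))
    best_n <- matrix(NA_real_, nrow(fm), ncol(fm))
    for (n in sort(as.integer(n_set))) {
      num <- shift_reflect(fm, dr * n, dc * n) + shift_reflect(fm, -dr * n, -dc * n)
      arg <- num / (2 * fm)
      ok <- den_ok & is.finite(arg) & abs(arg) <= 1
      better <- ok & (abs(arg) < best_abs)
      best_abs[better] <- abs(arg)[better]
      best_arg[better] <- arg[better]
      best_n[better] <- n
    }
    est <- acos(best_arg) / best_n
    list(est = est, valid = is.finite(best_abs) & best_abs <= 1)
  }
  x <- one_dir(1L, 0L)
  y <- one_dir(0L, 1L)
  valid <- x$valid & y$valid
  ifx <- x$est; ify <- y$est
  ifx[!valid] <- NA_real_
  ify[!valid] <- NA_real_
  list(ifx = ifx, ify = ify, valid = valid)
}

#' Reconstruct the FM image from an estimated IF field
#'
#' Integrates the IF field along a fixed path (down each column for `ifx`
#' after a first-row ramp accumulated from `ify`) and returns the cosine of
#' the integrated phase, the standard visualization of the FM part of a
#' demodulated texture.  Invalid pixels propagate as `NA`.
#'
#' @param ifx,ify IF component rasters in rad/pixel (`ify` optional).
#' @param valid optional logical raster of usable pixels.
#' @return matrix `cos(integrated phase)` with `NA` at invalid pixels.
#' @export
reconstruct_fm <- function(ifx, ify = NULL, valid = NULL) {
  ifx0 <- ifx
  ifx0[!is.finite(ifx0)] <- 0
  phase <- apply(ifx0, 2, cumsum)
  if (!is.null(ify)) {
    ramp <- ify[1, ]
    ramp[!is.finite(ramp)] <- 0
    phase <- phase + matrix(cumsum(ramp), nrow(ifx), ncol(ifx), byrow = TRUE)
  }
  out <- cos(phase)
  if (!is.null(valid)) out[!valid] <- NA_real_
  out[!is.finite(ifx)] <- NA_real_
  out
}

#' Multiscale AM-FM demodulation
#'
#' Runs the full demodulation chain: analytic image, channel filterbank,
#' per-scale dominant-component selection, and variable-spacing IF
#' estimation, separately for each requested frequency scale.
#'
#' @param image matrix or [gray_image()].
#' @param pixel_density pixels per mm (taken from the image attribute when
#'   present; defaults to the reference 16.66 px/mm).
#' @param scales character subset of `c("low", "medium", "high")`.
#' @param n_orient,flat_deg,edge_deg,radial_taper filterbank geometry, see
#'   [build_filterbank()].
#' @param floor validity floor for the IF estimator, see [estimate_if()].
#' @return an object of class `"amfm"`: a list with one element per scale
#'   (each holding `ia`, `phase`, `ifx`, `ify`, `valid`, `channel_index`),
#'   plus `pixel_density` and `dim`.  IF rasters are unsigned rad/pixel;
#'   [if_magnitude()] converts to cycles/mm.  A pixel is `valid` when the
#'   arccos estimator admits a spacing, the IA is nonnegligible, and the IF
#'   magnitude falls inside the scale's frequency range (out-of-band
#'   estimates, e.g. in smeared transition zones, are flagged invalid and
#'   excluded from the IF rasters).
#' @examples
#' y <- matrix(100 * cos(2 * pi * 12 / 128 * (0:127)), 128, 128, byrow = TRUE)
#' am <- amfm_demodulate(y, scales = "low")
#' summary(am)
#' @export
amfm_demodulate <- function(image, pixel_density = NULL,
                            scales = c("low", "medium", "high"),
                            n_orient = 4L, flat_deg = 15, edge_deg = 30,
                            radial_taper = 0.15, floor = 1e-3) {
  pd <- pixel_density %||% attr(image, "pixel_density") %||% 16.66
  m <- as_pixel_matrix(image)
  bands <- scale_bands(scales)
  analytic <- analytic_image(m)
  fb <- build_filterbank(dim(m), pixel_density = pd, bands = bands,
                         n_orient = n_orient, flat_deg = flat_deg,
                         edge_deg = edge_deg, radial_taper = radial_taper)
  res <- list()
  for (b in bands) {
    dc <- dominant_component(analytic, fb[[b$name]])
    fm <- cos(dc$phase)
    ife <- estimate_if(fm, n_set = b$n_set, floor = floor)
    # absolute amplitude floor scaled to the input: channel responses at the
    # level of FFT round-off (e.g. for content entirely outside the scale)
    # carry no phase information
    amp_ok <- dc$ia > 1e-8 * max(abs(m))
    # in-band validity: the IF magnitude must fall inside the scale's own
    # frequency range (out-of-band estimates are estimation failures and are
    # flagged, the dark regions of a low-scale IF rendering)
    ifm <- sqrt(ife$ifx^2 + ife$ify^2)
    lo <- 2 * pi * b$f_min / pd
    hi <- 2 * pi * b$f_max / pd
    in_band <- is.finite(ifm) & ifm >= lo & ifm <= hi
    valid <- ife$valid & amp_ok & in_band
    ifx <- ife$ifx; ify <- ife$ify
    ifx[!valid] <- NA_real_
    ify[!valid] <- NA_real_
    res[[b$name]] <- list(ia = dc$ia, phase = dc$phase, ifx = ifx, ify = ify,
                          valid = valid, channel_index = dc$channel_index)
  }
  structure(list(scales = res, pixel_density = pd, dim = dim(m)),
            class = "amfm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Instantaneous-frequency magnitude in cycles/mm
#'
#' @param x an `"amfm"` object.
#' @param scale scale name.
#' @return matrix `||grad phi|| = sqrt(ifx^2 + ify^2)` converted from
#'   rad/pixel to cycles/mm via the object's pixel density.
#' @export
if_magnitude <- function(x, scale = "low") {
  stopifnot(inherits(x, "amfm"))
  s <- x$scales[[scale]]
  if (is.null(s)) stop("scale '", scale, "' not present")
  sqrt(s$ifx^2 + s$ify^2) / (2 * pi) * x$pixel_density
}

#' @export
print.amfm <- function(x, ...) {
  cat(sprintf("amfm demodulation: %d x %d image, %.4g px/mm, scales: %s\n",
              x$dim[1], x$dim[2], x$pixel_density,
              paste(names(x$scales), collapse = ", ")))
  invisible(x)
}

#' @export
summary.amfm <- function(object, ...) {
  rows <- lapply(names(object$scales), function(nm) {
    s <- object$scales[[nm]]
    ifm <- sqrt(s$ifx^2 + s$ify^2) / (2 * pi) * object$pixel_density
    data.frame(scale = nm,
               valid_frac = mean(s$valid),
               ia_median = median(s$ia[s$valid]),
               if_median_cmm = median(ifm[s$valid], na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.amfm", "data.frame")
  out
}

#' @export
print.summary.amfm <- function(x, ...) {
  cat("per-scale AM-FM summary (IF in cycles/mm):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.amfm <- function(x, scale = names(x$scales)[1], what = c("ia", "ifmag"), ...) {
  what <- match.arg(what)
  s <- x$scales[[scale]]
  m <- if (what == "ia") log1p(s$ia) else {
    im <- sqrt(s$ifx^2 + s$ify^2); im[!s$valid] <- NA; im
  }
  m[!is.finite(m)] <- min(m[is.finite(m)])
  image(t(m[nrow(m):1, , drop = FALSE]), col = gray.colors(256), axes = FALSE,
        main = sprintf("%s %s", scale, if (what == "ia") "log IA" else "|IF|"), ...)
  invisible(x)
}
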