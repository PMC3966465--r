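#' Despeckle filter configuration
#'
#' Collects the tunable parameters shared by the eight despeckle filters.
#' Defaults follow common ultrasound practice: a 5 x 5 moving window with two
#' iterations for the local-statistics filters, diffusion parameters
#' `s2 = 2`, `alpha = 0.9`, step size `m = 0.2` for the coherence-enhancing
#' diffusion, and a 4-neighbour normalization `eta_s = 4` for the
#' speckle-reducing anisotropic diffusion.
#'
#' @param window odd moving-window side in pixels (default 5).
#' @param iterations number of filter passes for filters that are iterated
#'   (`NULL` uses each filter's own default: 2 for `lsmv`, `wiener` and
#'   `kuhawara`; 1 for `lsminsc`, `median` and `hybridmedian`).
#' @param noise_variance multiplicative-noise variance `sigma_n^2`; when
#'   `NULL` it is estimated from the image with [estimate_noise_variance()].
#' @param srad list with `eta_s` (divergence normalization) and `steps`.
#' @param nldif list with `s2` (coherence threshold), `alpha` (base
#'   diffusivity in (0, 1]), `m` (explicit step size), `steps`, and the
#'   Gaussian scales `sigma_grad` / `sigma_tensor` (pixels) used for the
#'   structure tensor.
#' @return a `filter_config` list.
#' @export
filter_config <- function(window = 5L, iterations = NULL, noise_variance = NULL,
                          srad = list(eta_s = 4, steps = 100L),
                          nldif = list(s2 = 2, alpha = 0.9, m = 0.2, steps = 10L,
                                       sigma_grad = 1, sigma_tensor = 2)) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("'window' must be odd and >= 3")
  if (!is.null(iterations) && iterations < 1L) stop("'iterations' must be >= 1")
  srad <- utils::modifyList(list(eta_s = 4, steps = 100L), srad)
  nldif <- utils::modifyList(list(s2 = 2, alpha = 0.9, m = 0.2, steps = 10L,
                                  sigma_grad = 1, sigma_tensor = 2), nldif)
  if (nldif$alpha <= 0 || nldif$alpha > 1) stop("nldif alpha must be in (0, 1]")
  if (nldif$s2 <= 0) stop("nldif s2 must be > 0")
  structure(list(window = window, iterations = iterations,
                 noise_variance = noise_variance, srad = srad, nldif = nldif),
            class = "filter_config")
}

#' Estimate the multiplicative-noise variance
#'
#' Speckle is approximately additive in the log domain, so the noise variance
#' `sigma_n^2` is estimated as the average over non-overlapping tiles of the
#' tile-wise sample variance of `log(1 + image)`.  Tiles must be considerably
#' larger than the filtering window so that local texture averages out.
#' Images containing negative values are shifted to be nonnegative before the
#' log (the phantom's cosine texture is signed; clinical images are not).
#'
#' @param image matrix or [gray_image()].
#' @param tile tile side in pixels (default 21).
#' @param window filtering-window side the estimate will be used with; the
#'   tile must be at least `4 * window`... see Details.
#' @details The precondition `tile >= 4 * window` enforces the "considerably
#'   larger" requirement; with the default 5 x 5 window any tile of 20 px or
#'   more qualifies.
#' @return the scalar noise-variance estimate (dimensionless, log-domain).
#' @examples
#' set.seed(1)
#' img <- matrix(expm1(3 + runif(256^2, -0.3, 0.3)), 256, 256)
#' estimate_noise_variance(img)  # ~ 0.03 = var of U(-0.3, 0.3)
#' @export
estimate_noise_variance <- function(image, tile = 21L, window = 5L) {
  tile <- as.integer(tile)
  if (tile < 4L * window)
    stop("'tile' must be at least 4x the filtering window (got ", tile,
         " for window ", window, ")")
  m <- as_pixel_matrix(image)
  if (nrow(m) < tile || ncol(m) < tile)
    stop("image smaller than one ", tile, "x", tile, " tile")
  if (min(m) < 0) m <- m - min(m)
  lg <- log1p(m)
  nr <- nrow(lg) %/% tile
  nc <- ncol(lg) %/% tile
  vs <- numeric(nr * nc)
  k <- 0L
  for (bi in seq_len(nr)) {
    rows <- ((bi - 1L) * tile + 1L):(bi * tile)
    for (bj in seq_len(nc)) {
      cols <- ((bj - 1L) * tile + 1L):(bj * tile)
      k <- k + 1L
      vs[k] <- var(as.vector(lg[rows, cols]))
    }
  }
  mean(vs)
}

#' Apply a despeckle filter
#'
#' Dispatches to one of the eight filters.  All windowed filters use
#' symmetric boundary reflection and compute every output pixel from the
#' input raster of the current pass (never in place), so results do not
#' depend on pixel visiting order.
#'
#' @param image matrix or [gray_image()], at least 5 x 5.
#' @param filter one of `"lsmv"`, `"wiener"`, `"kuhawara"`, `"lsminsc"`,
#'   `"median"`, `"hybridmedian"`, `"srad"`, `"nldif"`.
#' @param cfg a [filter_config()].
#' @return the filtered image, same type as the input.
#' @examples
#' tr <- generate_phantom(carotid_phantom_spec(height = 64L, width = 64L))
#' g <- add_speckle(tr, speckle_spec(0.07, seed = 1L))
#' f <- despeckle(g, "hybridmedian")
#' @export
despeckle <- function(image,
                      filter = c("lsmv", "wiener", "kuhawara", "lsminsc",
                                 "median", "hybridmedian", "srad", "nldif"),
                      cfg = filter_config()) {
  filter <- match.arg(filter)
  fn <- switch(filter,
    lsmv = dsf_lsmv, wiener = dsf_wiener, kuhawara = dsf_kuhawara,
    lsminsc = dsf_lsminsc, median = dsf_median, hybridmedian = dsf_hybrid_median,
    srad = dsf_srad, nldif = dsf_nldif)
  fn(image, cfg)
}

check_min_size <- function(m, w = 5L) {
  if (nrow(m) < w || ncol(m) < w) stop("image must be at least ", w, "x", w)
  m
}

iter_default <- function(cfg, default) {
  if (is.null(cfg$iterations)) default else as.integer(cfg$iterations)
}

noise_var_or_estimate <- function(m, cfg) {
  if (!is.null(cfg$noise_variance)) return(cfg$noise_variance)
  tile <- max(21L, 4L * cfg$window)
  if (nrow(m) >= tile && ncol(m) >= tile) estimate_noise_variance(m, tile, cfg$window)
  else var(as.vector(log1p(m - min(0, min(m)))))
}

#' Local-statistics despeckle filters
#'
#' `dsf_lsmv()` implements the first-order-statistics (Lee-type) filter
#' `f = gbar + k * (g - gbar)` with weight
#' `k = (sigma^2 - gbar^2 * sigma_n^2) / (sigma^2 * (1 + sigma_n^2))`
#' clipped to `[0, 1]`; `dsf_wiener()` uses the pixel-wise adaptive weight
#' `k = (sigma^2 - sigma_n^2) / sigma^2`.  Here `gbar` and `sigma^2` are the
#' mean and sample variance of the moving window and `sigma_n^2` the
#' multiplicative-noise variance.  Windows with zero variance fall back to
#' the local mean (`k = 0`).  Both run 2 iterations of a 5 x 5 window by
#' default.
#'
#' @inheritParams despeckle
#' @return the filtered image.
#' @name local_statistics_filters
NULL

lsmv_like <- function(image, cfg, weight_fn) {
  m <- check_min_size(as_pixel_matrix(image), cfg$window)
  sn2 <- noise_var_or_estimate(m, cfg)
  for (it in seq_len(iter_default(cfg, 2L))) {
    st <- local_mean_var(m, cfg$window)
    k <- weight_fn(st$mean, st$var, sn2)
    k[st$var <= 0] <- 0
    k <- pmin(pmax(k, 0), 1)
    m <- st$mean + k * (m - st$mean)
  }
  restore_image(m, image)
}

#' @rdname local_statistics_filters
#' @export
dsf_lsmv <- function(image, cfg = filter_config()) {
  lsmv_like(image, cfg, function(mn, vr, sn2) {
    (vr - mn^2 * sn2) / (vr * (1 + sn2))
  })
}

#' @rdname local_statistics_filters
#' @export
dsf_wiener <- function(image, cfg = filter_config()) {
  lsmv_like(image, cfg, function(mn, vr, sn2) (vr - sn2) / vr)
}

#' Homogeneous-mask-area despeckle filters
#'
#' `dsf_kuhawara()` scans the four 1 x 5 segments through each pixel
#' (horizontal, vertical and both diagonals) and replaces the pixel with the
#' median of the minimum-variance segment (2 iterations by default).
#' `dsf_lsminsc()` scans the nine 3 x 3 subwindows of the 5 x 5 neighbourhood
#' and replaces the pixel with the mean of the subwindow minimizing the
#' speckle index `C = sigma_s^2 / mean_s` computed on the log-compressed
#' raster (1 iteration).  Ties keep the first candidate in the fixed scan
#' order; subwindows with nonpositive log-domain mean are skipped.
#'
#' @inheritParams despeckle
#' @return the filtered image.
#' @name homogeneous_mask_filters
NULL

#' @rdname homogeneous_mask_filters
#' @export
dsf_kuhawara <- function(image, cfg = filter_config()) {
  m <- check_min_size(as_pixel_matrix(image))
  for (it in seq_len(iter_default(cfg, 2L))) m <- kuwahara_cpp(m)
  restore_image(m, image)
}

#' @rdname homogeneous_mask_filters
#' @export
dsf_lsminsc <- function(image, cfg = filter_config()) {
  m <- check_min_size(as_pixel_matrix(image))
  for (it in seq_len(iter_default(cfg, 1L))) {
    lg <- log1p(m - min(0, min(m)))
    m <- lsminsc_cpp(m, lg)
  }
  restore_image(m, image)
}

#' Median despeckle filters
#'
#' `dsf_median()` is the plain moving-window median (5 x 5 by default).
#' `dsf_hybrid_median()` averages the medians over three 5 x 5 windows: the
#' "+" cross, the "x" diagonal cross, and the full square, preserving fine
#' linear structure better than the plain median.  One iteration by default.
#'
#' @inheritParams despeckle
#' @return the filtered image.
#' @name median_filters
NULL

#' @rdname median_filters
#' @export
dsf_median <- function(image, cfg = filter_config()) {
  m <- check_min_size(as_pixel_matrix(image), cfg$window)
  for (it in seq_len(iter_default(cfg, 1L))) m <- median_filter_cpp(m, cfg$window)
  restore_image(m, image)
}

#' @rdname median_filters
#' @export
dsf_hybrid_median <- function(image, cfg = filter_config()) {
  m <- check_min_size(as_pixel_matrix(image))
  for (it in seq_len(iter_default(cfg, 1L))) m <- hybrid_median_cpp(m)
  restore_image(m, image)
}

#' Speckle-reducing anisotropic diffusion (SRAD)
#'
#' Iterates `f <- g + (1/eta_s) * div(c * grad g)` where the conduction
#' coefficient combines a normalized gradient magnitude and a normalized
#' Laplacian:
#' `c^2 = ((1/2)|grad g|^2 - (1/16)(lap g)^2) / (g + (1/4) lap g)^2`,
#' with `c` clipped to `[0, 1]` (negative `c^2` and zero denominators give
#' `c = 0`).  Gradients use central differences, the Laplacian the
#' 4-neighbour stencil, and the divergence the standard forward/backward
#' scheme, all with reflected boundaries.  Images with nonpositive values
#' are offset to be positive for the diffusivity and shifted back afterwards.
#'
#' @inheritParams despeckle
#' @return the filtered image.
#' @export
dsf_srad <- function(image, cfg = filter_config()) {
  m <- check_min_size(as_pixel_matrix(image))
  offset <- if (min(m) <= 0) 1 - min(m) else 0
  g <- m + offset
  eta <- cfg$srad$eta_s
  for (step in seq_len(cfg$srad$steps)) {
    gN <- shift_reflect(g, -1L, 0L); gS <- shift_reflect(g, 1L, 0L)
    gW <- shift_reflect(g, 0L, -1L); gE <- shift_reflect(g, 0L, 1L)
    lap <- gN + gS + gW + gE - 4 * g
    grad2 <- ((gS - gN) / 2)^2 + ((gE - gW) / 2)^2
    den <- (g + lap / 4)^2
    c2 <- (0.5 * grad2 - (1 / 16) * lap^2) / den
    c2[den == 0] <- 0
    cc <- sqrt(pmin(pmax(c2, 0), 1))
    cS <- shift_reflect(cc, 1L, 0L)
    cE <- shift_reflect(cc, 0L, 1L)
    dv <- cS * (gS - g) - cc * (g - gN) + cE * (gE - g) - cc * (g - gW)
    g <- g + dv / eta
  }
  restore_image(g - offset, image)
}

#' Coherence-enhancing nonlinear anisotropic diffusion
#'
#' Explicit time stepping of `dg/dt = div(D grad g)` with a symmetric
#' positive semidefinite diffusion tensor built from the local structure
#' tensor: the image is smoothed at scale `sigma_grad`, its gradient outer
#' product is smoothed componentwise at scale `sigma_tensor`, and the tensor
#' eigenvalues `mu1 >= mu2` measure local coherence.  Diffusivities are
#' `lambda2 = alpha` along the contour and
#' `lambda1 = alpha * (1 - (mu1 - mu2)^2 / s2)` across it while
#' `(mu1 - mu2)^2 <= s2`, dropping to 0 in strongly coherent regions so that
#' edges are preserved while speckle is diffused isotropically.
#'
#' @inheritParams despeckle
#' @return the filtered image.
#' @export
dsf_nldif <- function(image, cfg = filter_config()) {
  g <- check_min_size(as_pixel_matrix(image))
  p <- cfg$nldif
  kg <- gaussian_kernel(p$sigma_grad)
  kt <- gaussian_kernel(p$sigma_tensor)
  for (step in seq_len(p$steps)) {
    gs <- convolve_sep(g, kg)
    gx <- (shift_reflect(gs, 1L, 0L) - shift_reflect(gs, -1L, 0L)) / 2
    gy <- (shift_reflect(gs, 0L, 1L) - shift_reflect(gs, 0L, -1L)) / 2
    j11 <- convolve_sep(gx * gx, kt)
    j12 <- convolve_sep(gx * gy, kt)
    j22 <- convolve_sep(gy * gy, kt)
    if (!all(is.finite(j11)) || !all(is.finite(j12)) || !all(is.finite(j22)))
      stop("non-finite structure-tensor entries")
    tr2 <- (j11 + j22) / 2
    disc <- sqrt(((j11 - j22) / 2)^2 + j12^2)
    mu1 <- tr2 + disc
    mu2 <- tr2 - disc
    coh <- (mu1 - mu2)^2
    l1 <- ifelse(coh <= p$s2, p$alpha * (1 - coh / p$s2), 0)
    l2 <- p$alpha
    # dominant eigenvector (v1x, v1y); fall back to an axis when isotropic
    v1x <- j12
    v1y <- mu1 - j11
    nv <- sqrt(v1x^2 + v1y^2)
    small <- nv < 1e-12
    v1x <- ifelse(small, ifelse(j11 >= j22, 1, 0), v1x / pmax(nv, 1e-300))
    v1y <- ifelse(small, ifelse(j11 >= j22, 0, 1), v1y / pmax(nv, 1e-300))
    d11 <- l2 + (l1 - l2) * v1x^2
    d12 <- (l1 - l2) * v1x * v1y
    d22 <- l2 + (l1 - l2) * v1y^2
    Gx <- (shift_reflect(g, 1L, 0L) - shift_reflect(g, -1L, 0L)) / 2
    Gy <- (shift_reflect(g, 0L, 1L) - shift_reflect(g, 0L, -1L)) / 2
    fx <- d11 * Gx + d12 * Gy
    fy <- d12 * Gx + d22 * Gy
    dv <- (shift_reflect(fx, 1L, 0L) - shift_reflect(fx, -1L, 0L)) / 2 +
          (shift_reflect(fy, 0L, 1L) - shift_reflect(fy, 0L, -1L)) / 2
    g <- g + p$m * dv
  }
  restore_image(g, image)
}
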