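cfg1 <- function(noise_variance = 0.05, ...)
  filter_config(iterations = 1L, noise_variance = noise_variance, ...)

test_that("windowed filters match their brute-force oracles on random images", {
  for (seed in 1:3) {
    m <- random_image(16L, seed)
    sn2 <- 0.05
    expect_equal(unclass(dsf_lsmv(m, cfg1())), o_lsmv_once(m, sn2),
                 tolerance = 1e-12)
    expect_equal(unclass(dsf_wiener(m, cfg1())), o_lsmv_once(m, sn2, wiener = TRUE),
                 tolerance = 1e-12)
    expect_equal(unclass(dsf_kuhawara(m, cfg1())), o_kuwahara_once(m),
                 tolerance = 1e-12)
    expect_equal(unclass(dsf_lsminsc(m, cfg1())), o_lsminsc_once(m),
                 tolerance = 1e-12)
    expect_equal(unclass(dsf_median(m, cfg1())), o_median_once(m),
                 tolerance = 1e-12)
    expect_equal(unclass(dsf_hybrid_median(m, cfg1())), o_hybrid_once(m),
                 tolerance = 1e-12)
  }
})

test_that("default iteration counts compose the single-pass filters", {
  m <- random_image(16L, 9)
  cfg <- filter_config(noise_variance = 0.05)
  expect_equal(unclass(dsf_lsmv(m, cfg)),
               o_lsmv_once(o_lsmv_once(m, 0.05), 0.05), tolerance = 1e-12)
  expect_equal(unclass(dsf_kuhawara(m, cfg)),
               o_kuwahara_once(o_kuwahara_once(m)), tolerance = 1e-12)
})

test_that("all eight filters leave constant images unchanged exactly", {
  m <- matrix(77.5, 24, 24)
  for (f in c("lsmv", "wiener", "kuhawara", "lsminsc", "median",
              "hybridmedian", "srad", "nldif")) {
    out <- despeckle(m, f, filter_config(noise_variance = 0.05,
                                         srad = list(steps = 5L),
                                         nldif = list(steps = 3L)))
    expect_identical(unclass(out), m, label = f)
  }
})

test_that("lsmv/wiener weight limits give identity and box mean", {
  m <- random_image(16L, 4)
  # sigma_n^2 = 0: k = 1 so a single lsmv pass is the identity
  expect_equal(unclass(dsf_lsmv(m, cfg1(noise_variance = 0))), m,
               tolerance = 1e-12)
  # huge sigma_n^2: k clipped to 0 so wiener returns the 5x5 box mean
  box <- matrix(0, 16, 16)
  for (j in 1:16) for (i in 1:16)
    box[i, j] <- mean(o_window(m, i, j, -2:2, -2:2))
  expect_equal(unclass(dsf_wiener(m, cfg1(noise_variance = 1e9))), box,
               tolerance = 1e-12)
})

test_that("median filters reject impulses and preserve ramps", {
  m <- matrix(10, 9, 9); m[5, 5] <- 255
  expect_equal(unclass(dsf_median(m, cfg1()))[5, 5], 10)
  expect_equal(unclass(dsf_hybrid_median(m, cfg1()))[5, 5], 10)
  # monotone ramp: interior unchanged by the plain median
  ramp <- matrix(rep(1:20, each = 20), 20, 20)
  out <- unclass(dsf_median(ramp, cfg1()))
  expect_equal(out[3:18, 3:18], ramp[3:18, 3:18])
  # hybrid median = mean of its three sub-medians (compositional contract)
  m2 <- random_image(12L, 5)
  hm <- unclass(dsf_hybrid_median(m2, cfg1()))
  expect_equal(hm, o_hybrid_once(m2), tolerance = 1e-12)
})

test_that("kuhawara picks the homogeneous segment on a vertical edge", {
  # vertical edge: column 5 onwards bright; pixel on the edge has a
  # homogeneous vertical segment, so the output is that segment's median
  m <- matrix(0, 9, 9); m[, 5:9] <- 100
  set.seed(2); m <- m + matrix(runif(81, 0, 1e-3), 9, 9)  # break ties
  out <- unclass(dsf_kuhawara(m, cfg1()))
  vseg <- m[3:7, 5]
  vars <- c(var(m[5, 3:7]), var(vseg), var(diag(m[3:7, 3:7])),
            var(m[cbind(7:3, 3:7)]))
  expect_equal(which.min(vars), 2L)      # vertical is most homogeneous
  expect_equal(out[5, 5], median(vseg))
})

test_that("lsminsc picks the flattest 3x3 subwindow", {
  set.seed(3)
  m <- matrix(runif(81, 50, 200), 9, 9)
  m[3:5, 3:5] <- 80  # flat corner subwindow of the 5x5 around (5,5)
  out <- unclass(dsf_lsminsc(m, cfg1()))
  expect_equal(out[5, 5], mean(m[3:5, 3:5]))
})

test_that("range is preserved by the order-statistics filters", {
  m <- random_image(16L, 6)
  for (f in c("median", "hybridmedian", "kuhawara")) {
    out <- unclass(despeckle(m, f, cfg1()))
    expect_gte(min(out), min(m))
    expect_lte(max(out), max(m))
  }
})

test_that("srad single step matches the explicit stencil oracle", {
  g <- matrix(rep(seq(10, 50, length.out = 5), 5), 5, 5)  # 5x5 ramp
  cfg <- filter_config(srad = list(eta_s = 4, steps = 1L))
  expect_equal(unclass(dsf_srad(g, cfg)), o_srad_step(g, 4), tolerance = 1e-12)
  g2 <- random_image(12L, 7, lo = 10, hi = 200)
  expect_equal(unclass(dsf_srad(g2, cfg)), o_srad_step(g2, 4), tolerance = 1e-12)
})

test_that("srad conduction clips where the Laplacian term dominates", {
  # sharp impulse: at the impulse the Laplacian term exceeds the gradient
  # term so c^2 < 0 must clip to 0 and the impulse center must not diffuse
  # through the c = 0 coefficient at that site
  g <- matrix(100, 9, 9); g[5, 5] <- 101
  gN <- o_shift(g, -1, 0); gS <- o_shift(g, 1, 0)
  gW <- o_shift(g, 0, -1); gE <- o_shift(g, 0, 1)
  lap <- gN + gS + gW + gE - 4 * g
  grad2 <- ((gS - gN) / 2)^2 + ((gE - gW) / 2)^2
  expect_gt(lap[5, 5]^2 / 16, grad2[5, 5] / 2)   # clipping is exercised
  expect_equal(unclass(dsf_srad(g, filter_config(srad = list(steps = 1L)))),
               o_srad_step(g, 4), tolerance = 1e-12)
})

test_that("nldif diffusivity drops to zero in strongly coherent regions", {
  # a strong straight edge has (mu1 - mu2)^2 >> s2 = 2, so diffusion acts
  # only along the contour and the edge profile must not blur
  m <- matrix(0, 32, 32); m[, 17:32] <- 200
  cfg <- filter_config(nldif = list(steps = 5L))
  out <- unclass(dsf_nldif(m, cfg))
  mid <- abs(out[16, 16] - out[16, 17])
  expect_gt(mid, 150)  # edge contrast survives
  # whereas weak noise (low coherence) is smoothed nearly isotropically
  set.seed(8)
  n <- matrix(rnorm(32 * 32, 100, 0.01), 32, 32)
  outn <- unclass(dsf_nldif(n, cfg))
  expect_lt(sd(outn), sd(n))
})

test_that("nldif single explicit step matches a hand-built tensor update", {
  set.seed(11)
  g <- matrix(rnorm(15 * 15, 100, 5), 15, 15)
  p <- list(s2 = 2, alpha = 0.9, m = 0.2, steps = 1L, sigma_grad = 1, sigma_tensor = 2)
  out <- unclass(dsf_nldif(g, filter_config(nldif = p)))
  # oracle: same definitions, independent loop-based smoothing and stencil
  gk <- function(s) { r <- max(1, ceiling(3 * s)); k <- dnorm(-r:r, sd = s); k / sum(k) }
  sm <- function(m, kern) {
    r <- (length(kern) - 1) / 2
    t1 <- m * 0
    for (o in seq_along(kern)) t1 <- t1 + kern[o] * o_shift(m, o - r - 1, 0)
    t2 <- m * 0
    for (o in seq_along(kern)) t2 <- t2 + kern[o] * o_shift(t1, 0, o - r - 1)
    t2
  }
  gs <- sm(g, gk(1))
  gx <- (o_shift(gs, 1, 0) - o_shift(gs, -1, 0)) / 2
  gy <- (o_shift(gs, 0, 1) - o_shift(gs, 0, -1)) / 2
  j11 <- sm(gx * gx, gk(2)); j12 <- sm(gx * gy, gk(2)); j22 <- sm(gy * gy, gk(2))
  half <- (j11 + j22) / 2; disc <- sqrt(((j11 - j22) / 2)^2 + j12^2)
  mu1 <- half + disc; mu2 <- half - disc
  l1 <- ifelse((mu1 - mu2)^2 <= 2, 0.9 * (1 - (mu1 - mu2)^2 / 2), 0)
  v1x <- j12; v1y <- mu1 - j11
  nv <- sqrt(v1x^2 + v1y^2); small <- nv < 1e-12
  v1x <- ifelse(small, ifelse(j11 >= j22, 1, 0), v1x / pmax(nv, 1e-300))
  v1y <- ifelse(small, ifelse(j11 >= j22, 0, 1), v1y / pmax(nv, 1e-300))
  d11 <- 0.9 + (l1 - 0.9) * v1x^2; d12 <- (l1 - 0.9) * v1x * v1y
  d22 <- 0.9 + (l1 - 0.9) * v1y^2
  Gx <- (o_shift(g, 1, 0) - o_shift(g, -1, 0)) / 2
  Gy <- (o_shift(g, 0, 1) - o_shift(g, 0, -1)) / 2
  fx <- d11 * Gx + d12 * Gy; fy <- d12 * Gx + d22 * Gy
  dv <- (o_shift(fx, 1, 0) - o_shift(fx, -1, 0)) / 2 +
        (o_shift(fy, 0, 1) - o_shift(fy, 0, -1)) / 2
  expect_equal(out, g + 0.2 * dv, tolerance = 1e-12)
})

test_that("size preconditions and dispatcher names are enforced", {
  expect_error(dsf_median(matrix(1, 3, 3), cfg1()), "5x5")
  expect_error(despeckle(matrix(1, 8, 8), "nosuch"), "arg")
})

test_that("noise-variance estimator recovers an injected log-domain variance", {
  set.seed(21)
  v <- 0.04
  img <- matrix(expm1(4 + runif(256 * 256, -sqrt(3 * v), sqrt(3 * v))), 256, 256)
  est <- estimate_noise_variance(img, tile = 21L)
  expect_lt(abs(est - v) / v, 0.10)
  # constant image: exactly zero
  expect_equal(estimate_noise_variance(matrix(5, 64, 64)), 0)
  # tile must be considerably larger than the filtering window
  expect_error(estimate_noise_variance(img, tile = 5L, window = 5L), "4x")
  expect_error(estimate_noise_variance(matrix(1, 10, 10), tile = 21L), "tile")
})
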