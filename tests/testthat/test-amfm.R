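test_that("analytic image reproduces the input in its real part", {
  set.seed(1)
  m <- matrix(runif(48 * 40, 0, 255), 48, 40)
  a <- analytic_image(m)
  expect_lt(max(abs(Re(a) - m)), 1e-9)
  # constant image: DC preserved once, not doubled
  ac <- analytic_image(matrix(7, 16, 16))
  expect_lt(max(Mod(ac - 7)), 1e-9)
})

test_that("analytic image of an in-band column tone has unit modulus", {
  w0 <- 2 * pi * 12 / 128
  tone <- matrix(cos(w0 * (0:127)), 64, 128, byrow = TRUE)
  a <- analytic_image(tone)
  expect_lt(max(abs(Mod(a) - 1)), 1e-9)                # |exp(i w0 y)| = 1
  expect_lt(max(abs(a - exp(1i * w0 * (0:127))[col(a)])), 1e-9)
})

test_that("filterbank passbands convert cycles/mm to cycles/pixel", {
  fb <- build_filterbank(c(64L, 64L), pixel_density = 16.66,
                         bands = scale_bands("low"))
  expect_named(fb, "low")
  expect_length(fb$low, 4L)
  # digital band edges 1.04/16.66 .. 2.95/16.66 cycles/px: a frequency-grid
  # point well inside the band and at a sector center has full response
  u <- c(0:32, -31:-1) / 64
  r <- sqrt(outer(u^2, u^2, "+"))
  total <- Reduce(`+`, fb$low)
  mid <- sqrt(0.0624 * 0.177)  # geometric mid-band magnitude
  ring <- abs(r - mid) < 0.01
  expect_gt(max(total[ring]), 0.99)
  # all channel support in the retained (nonnegative column-frequency)
  # half-plane, none below/above the tapered band
  V <- matrix(ifelse((0:63) <= 32, (0:63), (0:63) - 64) / 64, 64, 64, byrow = TRUE)
  for (ch in fb$low) {
    expect_true(all(ch[V < 0] == 0))
    expect_true(all(ch[r < 0.0624 * 0.85 - 1e-9] == 0))
    expect_true(all(ch[r > 0.177 * 1.15 + 1e-9] == 0))
  }
  expect_error(build_filterbank(c(64L, 64L), pixel_density = 1,
                                bands = scale_bands("low")), "Nyquist")
})

test_that("a pure tone is maximal in the channel containing its orientation", {
  w0 <- 2 * pi * 12 / 96    # in-band magnitude at 16.66 px/mm
  tone <- matrix(cos(w0 * (0:95)), 96, 96, byrow = TRUE)  # 90-degree tone
  fb <- build_filterbank(c(96L, 96L), 16.66, scale_bands("low"))
  dc <- dominant_component(analytic_image(tone), fb$low)
  # channel 3 is centred at 90 degrees (centres 0, 45, 90, 135)
  expect_true(all(dc$channel_index == 3L))
  expect_lt(max(abs(dc$ia - 1)), 1e-6)
  # all-zero image: zero IA everywhere
  dz <- dominant_component(analytic_image(matrix(0, 32, 32)),
                           build_filterbank(c(32L, 32L), 16.66, scale_bands("low"))$low)
  expect_true(all(dz$ia == 0))
})

test_that("variable-spacing IF estimator is exact on cosines", {
  n <- 64L
  for (w0 in c(0.2, 0.5, 2 * pi * 7 / 64)) {
    fm <- matrix(cos(w0 * (0:(n - 1))), n, n)   # varies along rows
    est <- estimate_if(fm, n_set = 1:4)
    int <- 9:(n - 8)
    expect_lt(max(abs(est$ifx[int, int] - w0), na.rm = TRUE), 1e-9)
    expect_lt(max(abs(est$ify[int, int]), na.rm = TRUE), 1e-9)
  }
  # constant FM image: zero frequency
  e0 <- estimate_if(matrix(1, 16, 16), 1:4)
  expect_true(all(e0$valid))
  expect_true(all(e0$ifx == 0))
  expect_true(all(e0$ify == 0))
})

test_that("spacing selection minimizes the arccos argument", {
  w0 <- pi / 8
  fm <- matrix(cos(w0 * (0:63)), 64, 64)
  args <- abs(cos((1:4) * w0))
  expect_equal(which.min(args), 4L)   # spacing 4 has the smallest argument
  est <- estimate_if(fm, n_set = 1:4)
  sel <- est$valid[17:48, 17:48]      # rows at cos ~ 0 are flagged invalid
  expect_lt(max(abs(est$ifx[17:48, 17:48][sel] - w0)), 1e-12)
  # restricted spacing set still exact
  est1 <- estimate_if(fm, n_set = 1L)
  sel1 <- est1$valid[17:48, 17:48]
  expect_lt(max(abs(est1$ifx[17:48, 17:48][sel1] - w0)), 1e-12)
})

test_that("pixels near FM zeros are flagged invalid, not errors", {
  fm <- matrix(cos(pi / 2 * (0:31)), 32, 32)  # hits cos = 0 every other row
  est <- expect_silent(estimate_if(fm, n_set = 1:2))
  expect_true(any(!est$valid))
  expect_true(all(is.na(est$ifx[!est$valid])))
})

test_that("demodulation recovers a single in-band tone", {
  A <- 100
  w0 <- 2 * pi * 12 / 128    # bin-centred, low band at 16.66 px/mm
  img <- matrix(A * cos(w0 * (0:127)), 128, 128, byrow = TRUE)
  am <- amfm_demodulate(img, scales = "low")
  s <- am$scales$low
  int <- 17:112
  sel <- s$valid[int, int]
  expect_gt(mean(sel), 0.9)
  expect_lt(max(abs(s$ia[int, int] - A)) / A, 0.01)
  expect_lt(max(abs(s$ify[int, int][sel] - w0)), 1e-6)
  expect_lt(max(abs(s$ifx[int, int][sel])), 1e-6)
})

test_that("white noise yields a large invalid fraction at the low scale", {
  set.seed(5)
  img <- matrix(rnorm(128 * 128, 128, 30), 128, 128)
  am <- amfm_demodulate(img, scales = "low")
  expect_gt(mean(!am$scales$low$valid), 0.3)
})

test_that("out-of-band content is flagged invalid at other scales", {
  # a low-band tone analysed at the high scale must be mostly invalid
  w0 <- 2 * pi * 12 / 128
  img <- matrix(100 * cos(w0 * (0:127)), 128, 128, byrow = TRUE)
  am <- amfm_demodulate(img, scales = c("low", "high"))
  expect_gt(mean(am$scales$low$valid), 0.8)
  expect_gt(mean(!am$scales$high$valid), 0.8)
})

test_that("permuting channel order changes nothing but tie cases", {
  set.seed(6)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  fb <- build_filterbank(c(64L, 64L), 16.66, scale_bands("low"))
  a <- analytic_image(img)
  d1 <- dominant_component(a, fb$low)
  d2 <- dominant_component(a, rev(fb$low))
  expect_equal(d1$ia, d2$ia, tolerance = 1e-12)
  agree <- abs(d1$phase - d2$phase) < 1e-9
  expect_gt(mean(agree), 0.999)
})

test_that("FM reconstruction integrates a constant IF into a cosine ramp", {
  w0 <- 0.4
  ifx <- matrix(w0, 32, 32)
  ify <- matrix(0, 32, 32)
  rec <- reconstruct_fm(ifx, ify)
  expect_equal(rec, matrix(cos(w0 * (1:32)), 32, 32), tolerance = 1e-12)
  # invalid pixels propagate as NA
  valid <- matrix(TRUE, 32, 32); valid[1, 1] <- FALSE
  expect_true(is.na(reconstruct_fm(ifx, ify, valid)[1, 1]))
})

test_that("reconstruction from phantom truth correlates with the FM image", {
  w0 <- 2 * pi * 9 / 96
  bands <- data.frame(row_start = 0L, row_end = 95L, amplitude = 1,
                      ifx_min = w0, ifx_max = w0, ify_sign = -1)
  tr <- generate_phantom(phantom_spec(96L, 96L, bands))
  rec <- reconstruct_fm(tr$ifx_true, tr$ify_true)
  fmref <- unclass(tr$image)   # amplitude 1: pure FM part
  cc <- cor(as.vector(rec[9:88, 9:88]), as.vector(fmref[9:88, 9:88]))
  expect_gt(abs(cc), 0.9)
})

test_that("demodulating the noise-free phantom recovers in-band frequencies", {
  tr <- generate_phantom()
  am <- amfm_demodulate(tr$image, scales = "low")
  s <- am$scales$low
  # background interior: rows away from strips and image border
  bgrows <- c(33:257, 323:687, 767:992)
  sel <- s$valid[bgrows, 33:992]
  ifx <- s$ifx[bgrows, 33:992]
  tru <- tr$ifx_true[bgrows, 33:992]
  err <- abs(ifx[sel] - tru[sel])
  expect_lt(median(err), 1e-3)          # orders below the in-band 0.42..0.70
  expect_gt(mean(sel), 0.95)
})

test_that("if_magnitude converts to cycles/mm", {
  w0 <- 2 * pi * 12 / 128
  img <- matrix(100 * cos(w0 * (0:127)), 128, 128, byrow = TRUE)
  am <- amfm_demodulate(img, scales = "low")
  ifm <- if_magnitude(am, "low")
  expected <- w0 / (2 * pi) * 16.66
  expect_lt(abs(median(ifm[am$scales$low$valid]) - expected) / expected, 1e-6)
  expect_error(if_magnitude(am, "high"), "not present")
})
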