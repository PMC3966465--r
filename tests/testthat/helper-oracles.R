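# Brute-force per-pixel oracles for the windowed filters, written
# independently of the package internals (explicit loops, explicit index
# reflection).  Boundary convention shared with the package: symmetric
# (half-sample) reflection.

o_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

o_window <- function(m, i, j, ri, ci) {
  vals <- numeric(length(ri) * length(ci))
  k <- 0
  for (dj in ci) for (di in ri) {
    k <- k + 1
    vals[k] <- m[o_reflect(i + di, nrow(m)), o_reflect(j + dj, ncol(m))]
  }
  vals
}

o_segment <- function(m, i, j, dir) {
  vapply(-2:2, function(d)
    m[o_reflect(i + d * dir[1], nrow(m)), o_reflect(j + d * dir[2], ncol(m))], 0)
}

o_lsmv_once <- function(m, sn2, wiener = FALSE) {
  out <- m
  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m))) {
    w <- o_window(m, i, j, -2:2, -2:2)
    mn <- mean(w); vr <- var(w)
    k <- if (vr <= 0) 0 else if (wiener) (vr - sn2) / vr
         else (vr - mn^2 * sn2) / (vr * (1 + sn2))
    k <- min(max(k, 0), 1)
    out[i, j] <- mn + k * (m[i, j] - mn)
  }
  out
}

o_kuwahara_once <- function(m) {
  dirs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  out <- m
  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m))) {
    vs <- vapply(dirs, function(d) var(o_segment(m, i, j, d)), 0)
    best <- which.min(vs)                      # first minimum wins ties
    out[i, j] <- median(o_segment(m, i, j, dirs[[best]]))
  }
  out
}

o_lsminsc_once <- function(m) {
  lg <- log1p(m - min(0, min(m)))
  out <- m
  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m))) {
    best_c <- Inf; best_mean <- m[i, j]
    for (oi in -1:1) for (oj in -1:1) {
      wl <- o_window(lg, i + oi, j + oj, -1:1, -1:1)
      wg <- o_window(m, i + oi, j + oj, -1:1, -1:1)
      mn <- mean(wl)
      if (mn <= 0) next
      cc <- max(var(wl), 0) / mn
      if (cc < best_c) { best_c <- cc; best_mean <- mean(wg) }
    }
    out[i, j] <- best_mean
  }
  out
}

o_median_once <- function(m, w = 5L) {
  r <- w %/% 2L
  out <- m
  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m)))
    out[i, j] <- median(o_window(m, i, j, -r:r, -r:r))
  out
}

o_hybrid_once <- function(m) {
  out <- m
  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m))) {
    plus <- c(o_segment(m, i, j, c(1, 0)), o_segment(m, i, j, c(0, 1))[-3])
    cross <- c(o_segment(m, i, j, c(1, 1)), o_segment(m, i, j, c(1, -1))[-3])
    full <- o_window(m, i, j, -2:2, -2:2)
    out[i, j] <- mean(c(median(plus), median(cross), median(full)))
  }
  out
}

o_shift <- function(m, dr, dc) {
  out <- m
  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m)))
    out[i, j] <- m[o_reflect(i + dr, nrow(m)), o_reflect(j + dc, ncol(m))]
  out
}

# one explicit SRAD step on a positive image (eta-normalized divergence)
o_srad_step <- function(g, eta = 4) {
  gN <- o_shift(g, -1, 0); gS <- o_shift(g, 1, 0)
  gW <- o_shift(g, 0, -1); gE <- o_shift(g, 0, 1)
  lap <- gN + gS + gW + gE - 4 * g
  grad2 <- ((gS - gN) / 2)^2 + ((gE - gW) / 2)^2
  den <- (g + lap / 4)^2
  c2 <- (0.5 * grad2 - lap^2 / 16) / den
  c2[den == 0] <- 0
  cc <- sqrt(pmin(pmax(c2, 0), 1))
  dv <- o_shift(cc, 1, 0) * (gS - g) - cc * (g - gN) +
        o_shift(cc, 0, 1) * (gE - g) - cc * (g - gW)
  g + dv / eta
}

random_image <- function(n = 16L, seed = 1L, lo = 0, hi = 255) {
  set.seed(seed)
  matrix(runif(n * n, lo, hi), n, n)
}
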