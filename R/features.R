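#' AM-FM texture features for one image
#'
#' For each demodulated scale, computes 32-bin normalized histograms of the
#' instantaneous amplitude and of the IF magnitude (in cycles/mm) over the
#' pixels that are both valid and inside the region of interest, together
#' with scalar summaries (mean, SD, median and the 5/10/25/75/90/95
#' percentiles, linear-interpolation convention).  The per-image scalar
#' feature used for group statistics is the median, giving the six features
#' LIA/MIA/HIA (amplitude) and LIF/MIF/HIF (frequency).
#'
#' Histogram ranges are fixed so histograms are comparable across images:
#' IA bins span `[0, ia_max]` (supply the cohort-wide maximum via `ia_max`
#' for cross-image comparability) and IF bins span the scale's own
#' `[f_min, f_max]` in cycles/mm; values are clamped into range.
#'
#' @param amfm an `"amfm"` object from [amfm_demodulate()].
#' @param roi logical matrix region of interest (default: whole image).
#' @param ia_max upper edge of the IA histogram range (default: the image's
#'   own maximum IA over the selected pixels, per scale).
#' @param nbins number of histogram bins.
#' @return an `"amfm_features"` object: list with `hist` (per scale, `ia`
#'   and `ifmag` bin proportions), `summary` (data frame of scalar
#'   summaries) and `medians` (named vector LIA, MIA, HIA, LIF, MIF, HIF
#'   for the scales present).
#' @export
compute_features <- function(amfm, roi = NULL, ia_max = NULL, nbins = 32L) {
  stopifnot(inherits(amfm, "amfm"))
  if (is.null(roi)) roi <- matrix(TRUE, amfm$dim[1], amfm$dim[2])
  if (!identical(dim(roi), as.integer(amfm$dim)))
    stop("'roi' must match the image dimensions")
  bands <- scale_bands(names(amfm$scales))
  hists <- list()
  sums <- list()
  medians <- c()
  pr <- c(0.05, 0.10, 0.25, 0.75, 0.90, 0.95)
  for (nm in names(amfm$scales)) {
    s <- amfm$scales[[nm]]
    sel <- s$valid & roi
    if (!any(sel))
      stop("no valid ROI pixels at the '", nm, "' scale")
    ia <- s$ia[sel]
    ifm <- (sqrt(s$ifx^2 + s$ify^2) / (2 * pi) * amfm$pixel_density)[sel]
    b <- bands[[nm]]
    ia_hi <- ia_max %||% max(ia)
    hists[[nm]] <- list(
      ia = hist_fixed(ia, 0, ia_hi, nbins),
      ifmag = hist_fixed(ifm, b$f_min, b$f_max, nbins))
    stat <- function(v) c(mean = mean(v), std = sd(v), median = median(v),
                          quantile(v, pr, names = TRUE))
    sums[[nm]] <- rbind(ia = stat(ia), ifmag = stat(ifm))
    key <- toupper(substr(nm, 1, 1))
    medians[paste0(key, "IA")] <- median(ia)
    medians[paste0(key, "IF")] <- median(ifm)
  }
  summary_df <- do.call(rbind, lapply(names(sums), function(nm) {
    df <- as.data.frame(sums[[nm]])
    df$scale <- nm
    df$feature <- rownames(sums[[nm]])
    rownames(df) <- NULL
    df
  }))
  structure(list(hist = hists, summary = summary_df, medians = medians,
                 nbins = as.integer(nbins)),
            class = "amfm_features")
}

hist_fixed <- function(v, lo, hi, nbins) {
  if (hi <= lo) hi <- lo + 1
  v <- pmin(pmax(v, lo), hi)
  br <- seq(lo, hi, length.out = nbins + 1L)
  cnt <- tabulate(findInterval(v, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins)
  structure(cnt / sum(cnt), breaks = br)
}

#' @export
print.amfm_features <- function(x, ...) {
  cat("AM-FM feature table; per-image medians:\n")
  print(round(x$medians, 4))
  invisible(x)
}

# coerce a group (list of amfm_features, or matrix/data.frame of per-image
# scalar features) to a numeric matrix images x features
feature_matrix <- function(g) {
  if (inherits(g, "amfm_features")) g <- list(g)
  if (is.list(g) && !is.data.frame(g) && all(vapply(g, inherits, TRUE, "amfm_features"))) {
    m <- do.call(rbind, lapply(g, `[[`, "medians"))
  } else {
    m <- as.matrix(as.data.frame(g))
  }
  storage.mode(m) <- "double"
  m
}

#' Group summary of per-image features
#'
#' Summarizes the distribution of per-image median features over a group of
#' images by the mean, SD, median and 5/10/25/75/90/95 percentiles, scaled
#' by `scale_by` (100 by default, the conventional magnification for IA/IF
#' tables).
#'
#' @param tables list of [compute_features()] results (or a matrix/data
#'   frame of per-image features, one row per image).
#' @param scale_by multiplier applied to all reported values.
#' @return data frame with one row per feature.
#' @export
summarize_group <- function(tables, scale_by = 100) {
  m <- feature_matrix(tables)
  pr <- c(0.05, 0.10, 0.25, 0.75, 0.90, 0.95)
  out <- t(apply(m, 2, function(v) {
    c(mean = mean(v), std = if (length(v) > 1) sd(v) else 0,
      median = median(v), quantile(v, pr, names = TRUE)) * scale_by
  }))
  data.frame(feature = colnames(m), as.data.frame(out), row.names = NULL,
             check.names = FALSE)
}

#' Mann-Whitney comparison of two image groups
#'
#' Runs a two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature on the
#' per-image median feature values of two groups and flags significance at
#' `alpha` (0.05; no multiple-testing correction by default, matching common
#' practice for this screening table; set `p_adjust` for Bonferroni/FDR).
#' The score counts the significant features.
#'
#' @param group_a,group_b lists of [compute_features()] results or matrices
#'   of per-image features (one row per image, shared feature columns).
#' @param alpha significance level.
#' @param p_adjust optional multiple-testing correction method passed to
#'   [stats::p.adjust()] (e.g. `"bonferroni"`, `"BH"`); `"none"` by default.
#' @return an `"amfm_group_comparison"`: data frame with `feature`, `U`
#'   (rank-sum statistic for the first group), `p`, `significant`; the
#'   attribute `score` counts significant features.
#' @examples
#' a <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("LIA", "LIF")))
#' compare_groups(a, a + 5)
#' @export
compare_groups <- function(group_a, group_b, alpha = 0.05, p_adjust = "none") {
  ma <- feature_matrix(group_a)
  mb <- feature_matrix(group_b)
  common <- intersect(colnames(ma), colnames(mb))
  if (!length(common)) stop("groups share no features")
  if (nrow(ma) < 3L || nrow(mb) < 3L)
    warning("group with fewer than 3 images: p-values reported but low-powered")
  res <- lapply(common, function(f) {
    wt <- suppressWarnings(wilcox.test(ma[, f], mb[, f], alternative = "two.sided"))
    data.frame(feature = f, U = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- out$p_adjusted < alpha
  attr(out, "score") <- sum(out$significant)
  attr(out, "alpha") <- alpha
  class(out) <- c("amfm_group_comparison", "data.frame")
  out
}

#' @export
print.amfm_group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney feature screening (alpha = %g):\n", attr(x, "alpha")))
  df <- as.data.frame(x)
  df$p <- signif(df$p, 3)
  df$p_adjusted <- signif(df$p_adjusted, 3)
  print(df, row.names = FALSE)
  cat(sprintf("score (significant features): %d\n", attr(x, "score")))
  invisible(x)
}
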