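# Second-level Daubechies-2 (4-tap) wavelet detail statistics.
#
# The input is the bounding-box grayscale crop with zero background (the
# "final image" the pipeline produces for each nucleus). A 2-level 2-D DWT
# with half-point symmetric boundary extension is applied; the three
# second-level detail grids (horizontal, diagonal, vertical) each yield 8
# statistics: mean, median, max, min, range, sample standard deviation,
# median absolute deviation (unscaled, about the median) and mean absolute
# deviation (about the mean).

db2Filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  lo <- rev(h)                         # analysis low-pass
  hi <- h * c(-1, 1, -1, 1)            # quadrature mirror high-pass
  list(lo = lo, hi = hi)
}

# One DWT step along a vector: half-point symmetric extension by 3 samples,
# filter, downsample by 2.
dwtStep1d <- function(x, f) {
  n <- length(x)
  ext <- c(x[pmin(3:1, n)], x, x[pmax(n - (1:3) + 1L, 1L)])
  K <- (n + 3L) %/% 2L
  out <- numeric(K)
  for (k in seq_len(K)) {
    out[k] <- sum(f * ext[(2L * k - 1L):(2L * k + 2L)])
  }
  out
}

# Filter along rows (the horizontal axis) of a matrix.
dwtRows <- function(M, f) t(apply(M, 1L, dwtStep1d, f = f))

# One 2-D DWT level: returns approximation and the three detail grids.
# Horizontal detail = low-pass along the horizontal axis, high-pass along
# the vertical axis, so horizontal image structure (vertical intensity
# steps) lands in `h`.
dwt2Level <- function(M) {
  f <- db2Filters()
  loRows <- dwtRows(M, f$lo)   # filtered along x
  hiRows <- dwtRows(M, f$hi)
  list(
    a = t(dwtRows(t(loRows), f$lo)),
    h = t(dwtRows(t(loRows), f$hi)),
    v = t(dwtRows(t(hiRows), f$lo)),
    d = t(dwtRows(t(hiRows), f$hi))
  )
}

detailStats <- function(w) {
  v <- as.numeric(w)
  m <- mean(v); md <- median(v)
  c(mean_value = m, median_value = md, max_value = max(v),
    min_value = min(v), range_of_values = max(v) - min(v),
    standard_deviation = if (length(v) > 1) sd(v) else 0,
    median_absolute_deviation = median(abs(v - md)),
    mean_absolute_deviation = mean(abs(v - m)))
}

#' The 24 wavelet detail-coefficient features of a nucleus
#'
#' Two-level Daubechies-2 decomposition of the zero-background bounding-box
#' crop, symmetric boundary extension; 8 statistics on each of the three
#' second-level detail grids, ordered horizontal, diagonal, vertical.
#' Crops smaller than 8 x 8 (filter support exceeds the image) yield `NA`
#' for all 24 features.
#'
#' @param region a [NucleusRegion].
#' @return named numeric(24) (`dwt2h_*`, `dwt2d_*`, `dwt2v_*`).
#' @export
waveletFeatures <- function(region) {
  waveletFromPatch(regionPixels(region))
}

waveletFromPatch <- function(px) {
  nms <- featureNames63()[23:46]
  if (min(dim(px)) < 8L)
    return(setNames(rep(NA_real_, 24L), nms))
  l1 <- dwt2Level(px)
  l2 <- dwt2Level(l1$a)
  setNames(c(detailStats(l2$h), detailStats(l2$d), detailStats(l2$v)), nms)
}
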