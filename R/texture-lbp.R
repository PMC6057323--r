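# Local binary pattern features (R = 1, P = 8): per-pixel 8-bit codes
# thresholding the circular neighbors against the center, summarized by
# their mean and (population) standard deviation.

lbpOffsets <- function(R = 1, P = 8L) {
  a <- 2 * pi * (seq_len(P) - 1L) / P
  cbind(dr = R * sin(a), dc = R * cos(a))
}

# Bilinear sample of matrix m at (row + dr, col + dc) for all pixels in the
# given row/col index vectors (all sampled coordinates must be in range).
bilinearShift <- function(m, rows, cols, dr, dc) {
  rf <- rows + dr; cf <- cols + dc
  r0 <- floor(rf); c0 <- floor(cf)
  fr <- rf - r0; fc <- cf - c0
  r1 <- pmin(r0 + 1L, nrow(m)); c1 <- pmin(c0 + 1L, ncol(m))
  idx <- function(r, cc) m[cbind(r, cc)]
  (1 - fr) * (1 - fc) * idx(r0, c0) + (1 - fr) * fc * idx(r0, c1) +
    fr * (1 - fc) * idx(r1, c0) + fr * fc * idx(r1, c1)
}

#' The 2 local binary pattern features of a nucleus
#'
#' Codes `sum_p s(g_p - g_c) 2^p` with `s(x) = 1` for `x >= 0`, radius 1
#' and 8 neighbors sampled bilinearly on the circle, computed for in-mask
#' pixels whose full neighborhood lies inside the crop. A tolerance of
#' 1e-7 absorbs bilinear rounding when neighbor and center are equal.
#' Returns the mean and population standard deviation of the codes.
#'
#' @param region a [NucleusRegion].
#' @return named numeric(2): `local_binary_pattern_mean_value`,
#'   `local_binary_pattern_standard_deviation`.
#' @export
lbpFeatures <- function(region) {
  lbpFromPatch(regionPixels(region), regionMask(region))
}

lbpFromPatch <- function(px, mk) {
  nr <- nrow(px); nc <- ncol(px)
  nms <- c("local_binary_pattern_mean_value",
           "local_binary_pattern_standard_deviation")
  if (nr < 3L || nc < 3L)
    return(setNames(rep(NA_real_, 2L), nms))
  inner <- which(mk[2:(nr - 1L), 2:(nc - 1L), drop = FALSE])
  if (length(inner) == 0L)
    return(setNames(rep(NA_real_, 2L), nms))
  rows <- (inner - 1L) %% (nr - 2L) + 2L
  cols <- (inner - 1L) %/% (nr - 2L) + 2L
  gc <- px[cbind(rows, cols)]
  offs <- lbpOffsets()
  codes <- numeric(length(gc))
  for (p in seq_len(nrow(offs))) {
    gp <- bilinearShift(px, rows, cols, offs[p, 1L], offs[p, 2L])
    codes <- codes + (gp - gc >= -1e-7) * 2^(p - 1L)
  }
  m <- mean(codes)
  c(setNames(m, nms[1]),
    setNames(sqrt(mean((codes - m)^2)), nms[2]))
}
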