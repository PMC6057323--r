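# Gray-level co-occurrence matrix (GLCM) and the 13 Haralick features.

# Fixed 16 equal-width bins over [0,255]: bin width 16, levels 1..16.
quantize16 <- function(g, levels = 16L) {
  q <- 1L + floor(g / (256 / levels))
  q[q > levels] <- levels
  q
}

glcmOffsets <- function() {
  # (drow, dcol) for 0, 45, 90, 135 degrees in image coordinates
  list(deg0 = c(0L, 1L), deg45 = c(-1L, 1L),
       deg90 = c(-1L, 0L), deg135 = c(-1L, -1L))
}

#' Gray-level co-occurrence matrix of a nucleus
#'
#' Joint frequencies of quantized gray-level pairs at interpixel distance 1.
#' In-mask intensities are quantized into 16 equal-width bins of
#' `[0, 255]`; a pair is counted only when both pixels are in-mask. Each
#' directional matrix is counted in both directions (symmetric); the four
#' directional matrices are summed and normalized to total 1.
#'
#' @param region a [NucleusRegion] (or anything with `regionPixels()` /
#'   `regionMask()` methods).
#' @param directions subset of `c("deg0", "deg45", "deg90", "deg135")`.
#' @param levels number of gray levels (default 16).
#' @return `levels x levels` matrix of joint probabilities summing to 1.
#' @seealso [glcmFeatures()]
#' @export
glcm <- function(region, directions = c("deg0", "deg45", "deg90", "deg135"),
                 levels = 16L) {
  px <- regionPixels(region); mk <- regionMask(region)
  glcmFromPatch(px, mk, directions, levels)
}

glcmFromPatch <- function(px, mk, directions = names(glcmOffsets()),
                          levels = 16L) {
  q <- quantize16(px, levels)
  nr <- nrow(q); nc <- ncol(q)
  counts <- matrix(0, levels, levels)
  offs <- glcmOffsets()[directions]
  for (d in offs) {
    dr <- d[1]; dc <- d[2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1)) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    ok <- mk[r1, c1, drop = FALSE] & mk[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(ok)) next
    ij <- (a[ok] - 1L) * levels + b[ok]       # ordered pair (a, b)
    ji <- (b[ok] - 1L) * levels + a[ok]       # and its transpose
    counts <- counts + matrix(tabulate(ij, levels^2) +
                              tabulate(ji, levels^2), levels, levels,
                              byrow = TRUE)
  }
  tot <- sum(counts)
  if (tot == 0) stop("degenerate nucleus: no valid in-mask pixel pair")
  counts / tot
}

#' The 13 co-occurrence (Haralick) features
#'
#' Evaluates, on a normalized GLCM: angular second moment, contrast,
#' inverse difference moment, entropy, correlation, sum of squares
#' (variance), sum average, sum entropy, sum variance, difference variance,
#' difference entropy, and the two information measures of correlation.
#' Natural logarithms throughout with the convention `0 * log 0 = 0`;
#' correlation is defined 0 when either marginal standard deviation is 0,
#' and the first information measure is 0 when `max(HX, HY) = 0`.
#'
#' @param P normalized GLCM (entries sum to 1), levels indexed 1..Ng.
#' @return named numeric(13).
#' @export
glcmFeatures <- function(P) {
  Ng <- nrow(P)
  i <- row(P); j <- col(P)
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

  px <- rowSums(P); py <- colSums(P)
  mx <- sum(seq_len(Ng) * px); my <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - mx)^2 * px))
  sy <- sqrt(sum((seq_len(Ng) - my)^2 * py))

  # p_{x+y}(k), k = 2..2Ng and p_{x-y}(k), k = 0..Ng-1
  pxy_sum <- vapply(2:(2 * Ng), function(k) sum(P[i + j == k]), numeric(1))
  pxy_dif <- vapply(0:(Ng - 1), function(k) sum(P[abs(i - j) == k]),
                    numeric(1))
  ksum <- 2:(2 * Ng); kdif <- 0:(Ng - 1)

  ASM <- sum(P^2)
  CON <- sum(kdif^2 * pxy_dif)
  IDM <- sum(P / (1 + (i - j)^2))
  ENT <- -sum(xlogx(P))
  COR <- if (sx * sy == 0) 0 else (sum(i * j * P) - mx * my) / (sx * sy)
  SSQ <- sum((i - mx)^2 * P)
  SAVE <- sum(ksum * pxy_sum)
  SENT <- -sum(xlogx(pxy_sum))
  SVAR <- sum((ksum - SENT)^2 * pxy_sum)
  mu_dif <- sum(kdif * pxy_dif)
  DVAR <- sum((kdif - mu_dif)^2 * pxy_dif)
  DENT <- -sum(xlogx(pxy_dif))

  HX <- -sum(xlogx(px)); HY <- -sum(xlogx(py))
  HXY <- ENT
  pp <- outer(px, py)
  HXY1 <- -sum(ifelse(pp > 0, P * log(pp), 0))
  HXY2 <- -sum(xlogx(pp))
  ICM1 <- if (max(HX, HY) == 0) 0 else (HXY - HXY1) / max(HX, HY)
  ICM2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))

  c(angular_second_moment = ASM, contrast = CON,
    inverse_difference_moment = IDM, entropy = ENT, correlation = COR,
    sum_of_squares = SSQ, sum_average = SAVE, sum_entropy = SENT,
    sum_variance = SVAR, difference_variance = DVAR,
    difference_entropy = DENT,
    information_measure_correlation_1 = ICM1,
    information_measure_correlation_2 = ICM2)
}
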