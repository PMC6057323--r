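# Tamura texture features: coarseness (mean of the per-pixel best scale
# S_best and its 3-bin histogram), contrast, and roughness.

# Neighborhood means A_k over 2^k x 2^k windows via an integral image.
# Windows are clamped at the image border and divided by the actual pixel
# count, so A_k is defined everywhere.
windowMeans <- function(z, w) {
  nr <- nrow(z); nc <- ncol(z)
  # integral image: S[i+1, j+1] = sum z[1:i, 1:j]
  S <- matrix(0, nr + 1L, nc + 1L)
  cs <- apply(z, 2L, cumsum)                 # cumsum down rows
  if (nr == 1L) cs <- matrix(cs, 1L, nc)
  S[-1L, -1L] <- if (nc == 1L) cs else t(apply(cs, 1L, cumsum))
  lo <- -(w %/% 2L) + 1L; hi <- w %/% 2L + (w %% 2L)
  # window rows i+lo-1 .. i+hi-1 spans w pixels centered (even w: half-shift)
  r1 <- pmax(seq_len(nr) + lo - 1L, 1L); r2 <- pmin(seq_len(nr) + hi - 1L, nr)
  c1 <- pmax(seq_len(nc) + lo - 1L, 1L); c2 <- pmin(seq_len(nc) + hi - 1L, nc)
  sums <- S[r2 + 1L, c2 + 1L, drop = FALSE] -
          S[r1, c2 + 1L, drop = FALSE] -
          S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / cnt
}

# Shift a matrix by (dr, dc) with index clamping at the border.
shiftClamp <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[pmin(pmax(seq_len(nr) + dr, 1L), nr),
    pmin(pmax(seq_len(nc) + dc, 1L), nc), drop = FALSE]
}

#' The 6 Tamura features of a nucleus
#'
#' Coarseness: for each pixel and scale `k = 0..5`, neighborhood averages
#' over `2^k x 2^k` windows are differenced at offset `max(1, 2^(k-1))`
#' horizontally and vertically; the scale maximizing the larger difference
#' (ties broken to the smallest `k`) gives `S_best = 2^k`. Coarseness 1 is
#' the in-mask mean of `S_best`; coarseness 2-4 are the 3-bin equal-width
#' histogram of `S_best` over `[1, 32]`, in percent of in-mask pixels.
#' Contrast is `sigma / kurtosis^(1/4)` over in-mask intensities
#' (population moments; 0 when `sigma = 0`), and roughness is
#' coarseness 1 + contrast.
#'
#' @param region a [NucleusRegion].
#' @param kRange integer scales (default `0:5`).
#' @return named numeric(6): `tamura_coarseness_1` .. `_4`,
#'   `tamura_contrast`, `tamura_roughness`.
#' @export
tamuraFeatures <- function(region, kRange = 0:5) {
  tamuraFromPatch(regionPixels(region), regionMask(region), kRange)
}

tamuraFromPatch <- function(px, mk, kRange = 0:5) {
  if (!any(mk)) stop("degenerate nucleus: empty mask")
  nr <- nrow(px); nc <- ncol(px)
  bestE <- matrix(-Inf, nr, nc)
  Sbest <- matrix(2^kRange[1], nr, nc)
  for (k in kRange) {
    A <- windowMeans(px, 2L^k)
    d <- max(1L, 2L^(k - 1L))
    Eh <- abs(shiftClamp(A, 0L, d) - shiftClamp(A, 0L, -d))
    Ev <- abs(shiftClamp(A, d, 0L) - shiftClamp(A, -d, 0L))
    E <- pmax(Eh, Ev)
    sel <- E > bestE          # strict: ties keep the smaller k
    bestE[sel] <- E[sel]
    Sbest[sel] <- 2^k
  }
  sb <- Sbest[mk]
  crs1 <- mean(sb)
  smin <- 2^min(kRange); smax <- 2^max(kRange)
  breaks <- seq(smin, smax, length.out = 4L)
  h <- c(sum(sb <= breaks[2]),
         sum(sb > breaks[2] & sb <= breaks[3]),
         sum(sb > breaks[3]))
  hist3 <- 100 * h / length(sb)

  v <- px[mk]
  m <- mean(v)
  sigma <- sqrt(mean((v - m)^2))
  if (sigma == 0) {
    contrast <- 0
  } else {
    kurt <- mean((v - m)^4) / sigma^4
    contrast <- sigma / kurt^(1 / 4)
  }
  c(tamura_coarseness_1 = crs1, tamura_coarseness_2 = hist3[1],
    tamura_coarseness_3 = hist3[2], tamura_coarseness_4 = hist3[3],
    tamura_contrast = contrast,
    tamura_roughness = crs1 + contrast)
}
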