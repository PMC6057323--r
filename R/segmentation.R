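# Nucleus segmentation chain: grayscale -> smoothing -> Canny edges ->
# morphological closing + hole filling -> size filter -> logical AND with
# the grayscale image -> connected-component labeling.

#' Gaussian (or Laplacian-of-Gaussian) smoothing
#'
#' The smoothing stage of the segmentation chain: a Gaussian blur of
#' standard deviation `sigma` with reflective boundary handling, re-clipped
#' to `[0, 255]`. With `mode = "log"` a true Laplacian-of-Gaussian response
#' is computed instead and linearly rescaled to `[0, 255]` (band-pass
#' variant, off by default).
#'
#' @param img grayscale matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @param mode `"gaussian"` (default) or `"log"`.
#' @return smoothed grayscale matrix.
#' @export
smoothImage <- function(img, sigma = 2, mode = c("gaussian", "log")) {
  mode <- match.arg(mode)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a single positive number")
  k <- max(1L, ceiling(3 * sigma))
  xs <- -k:k
  if (mode == "gaussian") {
    g <- exp(-xs^2 / (2 * sigma^2))
    kern <- outer(g, g); kern <- kern / sum(kern)
  } else {
    r2 <- outer(xs^2, xs^2, "+")
    kern <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
    kern <- kern - mean(kern)
  }
  out <- convolveReflect(img, kern)
  if (mode == "log") {
    rng <- range(out)
    if (diff(rng) == 0) out[] <- 0
    else out <- (out - rng[1]) / diff(rng) * 255
  }
  pmin(pmax(out, 0), 255)
}

# 2-D convolution with reflective (mirror) boundary handling, via EBImage's
# FFT filter on a padded copy.
convolveReflect <- function(m, kern) {
  k <- (max(dim(kern)) - 1L) %/% 2L + 1L
  nr <- nrow(m); nc <- ncol(m)
  kr <- min(k, nr - 1L); kc <- min(k, nc - 1L)
  ri <- c(rev(seq_len(kr) + 1L), seq_len(nr), nr - seq_len(kr))
  ci <- c(rev(seq_len(kc) + 1L), seq_len(nc), nc - seq_len(kc))
  padded <- m[ri, ci, drop = FALSE]
  out <- EBImage::filter2(padded, kern, boundary = "circular")
  out[(kr + 1L):(kr + nr), (kc + 1L):(kc + nc), drop = FALSE]
}

otsuThreshold <- function(x, nbins = 256L) {
  # Otsu's criterion on a fixed histogram of x; returns a threshold value.
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- as.numeric(
    tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)),
             nbins))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(nbins))
  muT <- mu[nbins]; n <- w[nbins]
  between <- (muT * w - mu * n)^2 / (w * (n - w))
  between[!is.finite(between)] <- 0
  kbest <- which.max(between)
  rng[1] + kbest / nbins * diff(rng)
}

#' Canny edge detection
#'
#' Gradient magnitude (Sobel), non-maximum suppression to one-pixel-wide
#' ridges, and double-threshold hysteresis. Thresholds are fractions of the
#' gradient-magnitude maximum; with `low`/`high` = `NA` the high threshold
#' is set by Otsu's method on the gradient magnitudes and `low = 0.4 * high`.
#'
#' @param img smoothed grayscale matrix.
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude, or `NA` for automatic selection.
#' @return logical edge mask of the same shape.
#' @export
detectEdges <- function(img, low = NA_real_, high = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- convolveReflect(img, sx)         # gradient along columns (x)
  gy <- convolveReflect(img, t(sx))      # gradient along rows (y)
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  # guard against FFT round-off on flat images
  if (mmax <= 1e-6) return(matrix(FALSE, nr, nc))

  if (is.na(high)) {
    high <- otsuThreshold(mag) / mmax
    low <- 0.4 * high
  } else if (is.na(low)) low <- 0.4 * high

  # non-maximum suppression: quantize gradient direction into 4 sectors and
  # compare against the two neighbors along the gradient
  ang <- atan2(gy, gx)                   # (-pi, pi]
  sector <- (round(ang / (pi / 4)) %% 4L)  # 0:horiz,1:diag,2:vert,3:anti-diag
  shift <- function(m, dr, dc) {
    out <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }
  keep <- matrix(FALSE, nr, nc)
  nbr <- list(`0` = c(0L, 1L), `1` = c(1L, 1L),
              `2` = c(1L, 0L), `3` = c(1L, -1L))
  for (s in 0:3) {
    d <- nbr[[as.character(s)]]
    sel <- sector == s
    keep[sel] <- mag[sel] >= pmax(shift(mag, d[1], d[2])[sel],
                                  shift(mag, -d[1], -d[2])[sel])
  }
  strong <- keep & (mag >= high * mmax)
  weak <- keep & (mag >= low * mmax)
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  # hysteresis: keep weak components containing at least one strong pixel
  lab <- labelComponents(weak)
  good <- unique(lab[strong])
  lab > 0 & matrix(lab %in% good, nr, nc)
}

# 8-connected component labeling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally with a union-find pass.
labelComponents <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) {
    ra <- findRoot(a); rb <- findRoot(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1L), if (d[2] > 0) seq_len(nc - 1L) else 2L:nc,
             drop = FALSE]
    b <- lab[2L:nr, if (d[2] > 0) 2L:nc else seq_len(nc - 1L), drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      pairs <- unique(cbind(a[sel], b[sel]))
      for (i in seq_len(nrow(pairs))) union2(pairs[i, 1], pairs[i, 2])
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

#' Morphological closing and hole filling
#'
#' Closes the edge mask with a disk structuring element and flood-fills
#' enclosed holes, turning closed nuclear outlines into solid blobs.
#'
#' @param edges logical edge mask.
#' @param closingRadius disk radius in pixels (0 skips the closing).
#' @return logical mask of filled blobs.
#' @export
closeAndFill <- function(edges, closingRadius = 3L) {
  m <- edges * 1L
  if (closingRadius > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(closingRadius) + 1L, "disc")
    m <- EBImage::closing(m, brush)
  }
  EBImage::fillHull(m) > 0
}

#' Size filtering of candidate blobs
#'
#' Removes 8-connected components smaller than `minArea` pixels and,
#' optionally, components touching the image border (whose morphology would
#' be truncated).
#'
#' @param mask logical mask of filled blobs.
#' @param minArea minimum component area in pixels (the chain's preset
#'   threshold; default 500).
#' @param discardBorder drop components touching the frame border.
#' @return logical mask.
#' @export
sizeFilter <- function(mask, minArea = 500L, discardBorder = TRUE) {
  lab <- labelComponents(mask)
  n <- max(lab)
  if (n == 0L) return(mask & FALSE)
  areas <- tabulate(lab[lab > 0L], n)
  drop <- areas < minArea
  if (discardBorder) {
    borderLabs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                           lab[, ncol(lab)]))
    drop[setdiff(borderLabs, 0L)] <- TRUE
  }
  keep <- which(!drop)
  lab > 0L & matrix(lab %in% keep, nrow(lab), ncol(lab))
}

#' Mask a grayscale image (logical AND)
#'
#' Keeps pixel values where the mask is TRUE, sets 0 elsewhere.
#'
#' @param gray grayscale matrix.
#' @param mask logical mask of the same shape.
#' @return masked grayscale matrix.
#' @export
applyMask <- function(gray, mask) {
  if (!identical(dim(gray), dim(mask)))
    stop("image and mask shapes differ")
  gray * mask
}

#' Segment nuclei from a microscopy image
#'
#' Runs the full segmentation chain (grayscale conversion, smoothing, Canny
#' edge detection, morphological closing + hole filling, size and border
#' filtering, logical AND with the grayscale image) and labels the resulting
#' 8-connected components. Deterministic for fixed input and parameters.
#'
#' @param img RGB array or grayscale matrix.
#' @param params a [SegmentationParams] object.
#' @return list of [NucleusRegion] objects sorted by bounding-box
#'   `(row0, col0)`.
#' @examples
#' set.seed(1)
#' sp <- nucleusSpec(center = c(48, 48), baseRadius = 16)
#' im <- renderImage(list(sp), groupParams("low_like"), c(96, 96), seed = 1)
#' regs <- segmentNuclei(im$image, segmentationParams())
#' length(regs)
#' @export
segmentNuclei <- function(img, params = segmentationParams()) {
  gray <- toGrayscale(img)
  sm <- smoothImage(gray, params@smoothingSigma, params@smoothingMode)
  edges <- detectEdges(sm, params@cannyLow, params@cannyHigh)
  blobs <- closeAndFill(edges, params@closingRadius)
  kept <- sizeFilter(blobs, params@minArea)
  masked <- applyMask(gray, kept)
  extractRegions(masked, kept)
}

# Build NucleusRegion objects from a masked grayscale image and its final
# binary mask; regions sorted by (row0, col0) of the bounding box.
extractRegions <- function(masked, mask) {
  lab <- labelComponents(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  regs <- vector("list", n)
  idx <- which(lab > 0L)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  labs <- lab[idx]
  for (i in seq_len(n)) {
    sel <- labs == i
    r <- rows[sel]; cc <- cols[sel]
    r0 <- min(r); r1 <- max(r); c0 <- min(cc); c1 <- max(cc)
    mcrop <- lab[r0:r1, c0:c1, drop = FALSE] == i
    pcrop <- masked[r0:r1, c0:c1, drop = FALSE] * mcrop
    regs[[i]] <- new("NucleusRegion", label = i,
                     bbox = as.integer(c(r0 - 1L, c0 - 1L, r1, c1)),
                     mask = mcrop, pixels = pcrop, area = sum(mcrop))
  }
  ord <- order(vapply(regs, function(x) x@bbox[1], integer(1)),
               vapply(regs, function(x) x@bbox[2], integer(1)))
  regs <- regs[ord]
  for (i in seq_along(regs)) regs[[i]]@label <- i
  regs
}
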