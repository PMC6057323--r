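# Morphology (regionprops-style) features of a single-component binary mask.

# Moore-neighbor boundary trace of the outer contour (8-connected), returning
# the chain of boundary pixel coordinates in order.
traceBoundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  fg <- which(pad)
  start <- fg[1L]  # column-major: topmost pixel of leftmost column
  sr <- (start - 1L) %% (nr + 2L) + 1L
  sc <- (start - 1L) %/% (nr + 2L) + 1L
  # clockwise Moore neighborhood starting from W
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  chain <- matrix(0L, sum(pad) * 4L + 8L, 2L)
  chain[1L, ] <- c(sr, sc)
  nchain <- 1L
  prevDir <- 1L  # came from the west (backtrack points W)
  cr <- sr; cccol <- sc
  repeat {
    found <- FALSE
    for (s in 0:7) {
      d <- (prevDir - 1L + s) %% 8L + 1L
      rr <- cr + dr[d]; cc2 <- cccol + dc[d]
      if (pad[rr, cc2]) {
        nchain <- nchain + 1L
        chain[nchain, ] <- c(rr, cc2)
        # restart the clockwise scan two steps back from the entry direction
        prevDir <- ((d - 2L - 1L) %% 8L) + 1L
        cr <- rr; cccol <- cc2
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (cr == sr && cccol == sc) break
    if (nchain >= nrow(chain)) break  # safety
  }
  chain[seq_len(nchain), , drop = FALSE] - 1L  # unpad
}

# Perimeter: sum of boundary chain step lengths (1 axial, sqrt(2) diagonal).
chainPerimeter <- function(chain) {
  if (nrow(chain) < 2L) return(0)
  steps <- abs(diff(chain))
  sum(ifelse(rowSums(steps) == 2L, sqrt(2), 1))
}

# Pixel count of the filled convex hull of the foreground pixel centers.
convexAreaPixels <- function(rows, cols) {
  pts <- unique(cbind(cols, rows))            # (x, y)
  if (nrow(pts) <= 2L) return(nrow(pts))
  h <- chull(pts[, 1L], pts[, 2L])            # clockwise indices
  hull <- pts[rev(h), , drop = FALSE]         # counter-clockwise
  nh <- nrow(hull)
  if (nh < 3L) return(length(rows))
  # degenerate (collinear) hull
  area2 <- sum(hull[, 1L] * hull[c(2:nh, 1L), 2L] -
               hull[c(2:nh, 1L), 1L] * hull[, 2L])
  if (abs(area2) < 1e-9) return(length(rows))
  gx <- seq(min(pts[, 1L]), max(pts[, 1L]))
  gy <- seq(min(pts[, 2L]), max(pts[, 2L]))
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  inside <- rep(TRUE, length(px))
  tol <- 1e-9
  for (k in seq_len(nh)) {
    a <- hull[k, ]; b <- hull[if (k == nh) 1L else k + 1L, ]
    cross <- (b[1L] - a[1L]) * (py - a[2L]) - (b[2L] - a[2L]) * (px - a[1L])
    inside <- inside & (cross >= -tol)
  }
  sum(inside)
}

#' The 9 morphology features of a nucleus mask
#'
#' Regionprops-style shape descriptors of a single 8-connected component:
#' area (pixel count); perimeter (8-connected outer boundary chain length,
#' diagonal steps weighted sqrt(2)); equivalent diameter
#' `sqrt(4 area / pi)`; convex area (pixel count of the filled convex hull
#' of pixel centers); major and minor axis lengths and eccentricity of the
#' ellipse with the same normalized second central moments (with the +1/12
#' per-pixel variance correction); solidity (area / convex area); and
#' extent (area / bounding-box area).
#'
#' @param mask logical matrix containing exactly one 8-connected foreground
#'   component.
#' @return named numeric(9), names `featureNames63()[55:63]`.
#' @examples
#' sq <- matrix(TRUE, 10, 10)
#' morphologyVector(sq)[c("nucleus_area", "nucleus_solidity")]
#' @export
morphologyVector <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  area <- sum(mask)
  if (area == 0L) stop("empty mask")
  lab <- labelComponents(mask)
  if (max(lab) != 1L) stop("mask must contain exactly one component, found ",
                           max(lab))
  idx <- which(mask)
  rows <- (idx - 1L) %% nrow(mask) + 1L
  cols <- (idx - 1L) %/% nrow(mask) + 1L

  perim <- chainPerimeter(traceBoundary(mask))
  eqd <- sqrt(4 * area / pi)
  convArea <- convexAreaPixels(rows, cols)

  # moment ellipse with the +1/12 pixel-variance correction
  mu20 <- mean((cols - mean(cols))^2) + 1 / 12
  mu02 <- mean((rows - mean(rows))^2) + 1 / 12
  mu11 <- mean((cols - mean(cols)) * (rows - mean(rows)))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  major <- 2 * sqrt(2) * sqrt(mu20 + mu02 + common)
  minor <- 2 * sqrt(2) * sqrt(max(mu20 + mu02 - common, 0))
  ecc <- if (major == 0) 0 else sqrt(max(1 - (minor / major)^2, 0))

  bboxArea <- (max(rows) - min(rows) + 1L) * (max(cols) - min(cols) + 1L)
  setNames(
    c(area, perim, eqd, convArea, major, minor, ecc,
      area / convArea, area / bboxArea),
    featureNames63()[55:63]
  )
}
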