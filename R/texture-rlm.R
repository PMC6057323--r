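# Gray-level run-length matrix features: short-run emphasis, long-run
# emphasis, gray-level nonuniformity, run-length nonuniformity, run
# percentage. Runs of equal quantized level are traced along each of the
# four directions within the mask (a run breaks at the mask boundary);
# the five ratios are computed per direction and averaged.

# All scan lines of a matrix along a direction, as lists of linear indices.
scanLines <- function(nr, nc, direction) {
  idx <- matrix(seq_len(nr * nc), nr, nc)
  switch(direction,
    deg0   = lapply(seq_len(nr), function(r) idx[r, ]),
    deg90  = lapply(seq_len(nc), function(cc) idx[, cc]),
    deg45  = { # bottom-left to top-right
      split(idx[order(row(idx) + col(idx), -row(idx))],
            sort(row(idx) + col(idx)))
    },
    deg135 = { # top-left to bottom-right
      split(idx[order(col(idx) - row(idx), row(idx))],
            sort(col(idx) - row(idx)))
    },
    stop("unknown direction ", direction))
}

# Run-length counts Q[level, runlength] for one direction.
runLengthMatrix <- function(q, mk, direction, levels = 16L) {
  nr <- nrow(q); nc <- ncol(q)
  maxRun <- max(nr, nc)
  Q <- matrix(0L, levels, maxRun)
  for (line in scanLines(nr, nc, direction)) {
    v <- q[line]
    v[!mk[line]] <- NA_integer_
    r <- rle(v)
    keep <- !is.na(r$values)
    if (!any(keep)) next
    for (k in which(keep)) {
      Q[r$values[k], r$lengths[k]] <- Q[r$values[k], r$lengths[k]] + 1L
    }
  }
  Q
}

rlmStats <- function(Q, P) {
  tot <- sum(Q)
  jj <- col(Q)
  c(short_run_emphasis = sum(Q / jj^2) / tot,
    long_run_emphasis = sum(Q * jj^2) / tot,
    gray_level_nonuniformity = sum(rowSums(Q)^2) / tot,
    run_length_nonuniformity = sum(colSums(Q)^2) / tot,
    run_percentage = tot / P)
}

#' The 5 run-length features of a nucleus
#'
#' In-mask intensities are quantized to 16 levels (as for the GLCM); runs of
#' equal level are traced along the four directions (0, 45, 90, 135
#' degrees), breaking at the mask boundary. The five statistics are
#' computed per direction with `P` the in-mask pixel count, then averaged
#' over directions.
#'
#' @param region a [NucleusRegion].
#' @param directions subset of `c("deg0", "deg45", "deg90", "deg135")`.
#' @param levels number of gray levels (default 16).
#' @return named numeric(5): `short_run_emphasis`, `long_run_emphasis`,
#'   `gray_level_nonuniformity`, `run_length_nonuniformity`,
#'   `run_percentage`.
#' @export
rlmFeatures <- function(region,
                        directions = c("deg0", "deg45", "deg90", "deg135"),
                        levels = 16L) {
  px <- regionPixels(region); mk <- regionMask(region)
  rlmFromPatch(px, mk, directions, levels)
}

rlmFromPatch <- function(px, mk,
                         directions = c("deg0", "deg45", "deg90", "deg135"),
                         levels = 16L) {
  P <- sum(mk)
  if (P == 0) stop("degenerate nucleus: empty mask")
  q <- quantize16(px, levels)
  per <- vapply(directions,
                function(d) rlmStats(runLengthMatrix(q, mk, d, levels), P),
                numeric(5))
  rowMeans(per)
}
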