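# Histogram features and the assembled 54-feature texture vector.

#' The 4 histogram features of a nucleus
#'
#' Mean, standard deviation, skewness and (non-excess) kurtosis of the
#' in-mask intensities, with population (1/N) denominators throughout.
#' When the standard deviation is 0, skewness and kurtosis are undefined
#' and returned as `NA`.
#'
#' @param region a [NucleusRegion].
#' @return named numeric(4): `mean_value`, `standard_deviation`,
#'   `skewness`, `kurtosis`.
#' @export
histogramFeatures <- function(region) {
  histogramFromPatch(regionPixels(region), regionMask(region))
}

histogramFromPatch <- function(px, mk) {
  v <- px[mk]
  if (length(v) < 2L) stop("degenerate nucleus: fewer than 2 in-mask pixels")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0) {
    sk <- NA_real_; ku <- NA_real_
  } else {
    sk <- mean((v - m)^3) / s^3
    ku <- mean((v - m)^4) / s^4
  }
  c(mean_value = m, standard_deviation = s, skewness = sk, kurtosis = ku)
}

#' The 54-feature texture vector of a nucleus
#'
#' Concatenation, in canonical order, of the six texture families:
#' histogram (4), co-occurrence (13), run-length (5), wavelet (24),
#' Tamura (6) and local binary pattern (2). A family that is undefined for
#' a degenerate region contributes `NA` values rather than aborting.
#'
#' @param region a [NucleusRegion].
#' @return named numeric(54), names `featureNames63()[1:54]`.
#' @seealso [nucleusFeatures()] for the full 63-feature vector.
#' @export
textureVector <- function(region) {
  nms <- featureNames63()[1:54]
  safely <- function(expr, n, names) {
    out <- tryCatch(expr, error = function(e) setNames(rep(NA_real_, n),
                                                       names))
    out
  }
  out <- c(
    safely(histogramFeatures(region), 4L, nms[1:4]),
    safely(glcmFeatures(glcm(region)), 13L, nms[5:17]),
    safely(rlmFeatures(region), 5L, nms[18:22]),
    safely(waveletFeatures(region), 24L, nms[23:46]),
    safely(tamuraFeatures(region), 6L, nms[47:52]),
    safely(lbpFeatures(region), 2L, nms[53:54])
  )
  stopifnot(identical(names(out), nms))
  out
}

#' The full 63-feature vector of a nucleus
#'
#' Texture (items 1-54) plus morphology (items 55-63), in canonical order.
#'
#' @param region a [NucleusRegion].
#' @return named numeric(63).
#' @export
nucleusFeatures <- function(region) {
  combineVectors(textureVector(region), morphologyVector(regionMask(region)))
}

#' Combine texture and morphology vectors
#'
#' Concatenates a 54-value texture vector and a 9-value shape descriptor
#' into the ordered 63-feature record, preserving missing values.
#'
#' @param texture named numeric(54) from [textureVector()].
#' @param shape named numeric(9) from [morphologyVector()].
#' @return named numeric(63) in canonical order.
#' @export
combineVectors <- function(texture, shape) {
  nms <- featureNames63()
  if (!identical(names(texture), nms[1:54]))
    stop("'texture' must be a named 54-feature vector in canonical order")
  if (!identical(names(shape), nms[55:63]))
    stop("'shape' must be a named 9-feature vector in canonical order")
  c(texture, shape)
}
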