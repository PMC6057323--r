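#' @importFrom grDevices chull
#' @importFrom utils read.csv write.csv
#' @importFrom stats median sd cor rnorm runif setNames
NULL

# Images are plain numeric matrices (grayscale, 8-bit integer values in
# [0, 255], dim = c(height, width)) or height x width x 3 arrays (RGB).
# Indexing is row-major (row, col), top-left origin.

pngBitDepth <- function(path) {
  # IHDR bit depth lives at byte offset 24 (after signature + length + type
  # + width + height)
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) stop("corrupt or truncated PNG: ", path)
  as.integer(hdr[25L])
}

#' Read a microscopy image
#'
#' Reads a TIFF or PNG image as an 8-bit grayscale matrix or RGB array.
#' 16-bit inputs are rescaled to 8 bits by integer division by 257 (fixed
#' rescale, not per-image min-max, so intensities stay comparable across
#' images). 4-channel inputs drop the alpha channel with a warning;
#' 2-channel inputs are rejected.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @return numeric matrix (grayscale) or height x width x 3 array (RGB),
#'   integer values in `[0, 255]`.
#' @seealso [toGrayscale()], [writeGrayImage()]
#' @examples
#' f <- tempfile(fileext = ".png")
#' writeGrayImage(matrix(0:255, 16, 16), f)
#' img <- readMicroscopyImage(f)
#' @export
readMicroscopyImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    if (is.list(raw)) raw <- raw[[1L]]
    vals <- raw
    if (max(vals) > 255) vals <- vals %/% 257L  # 16-bit -> 8-bit
  } else if (ext == "png") {
    depth <- pngBitDepth(path)
    raw <- png::readPNG(path)
    vals <- round(raw * (2^depth - 1))
    if (depth == 16) vals <- vals %/% 257L
  } else {
    stop("unsupported image format: ", ext, " (use TIFF or PNG)")
  }
  if (length(dim(vals)) == 2L) return(vals)
  nch <- dim(vals)[3L]
  if (nch == 4L) {
    warning("4-channel image: dropping alpha channel")
    vals <- vals[, , 1:3, drop = FALSE]
  } else if (nch != 3L) {
    stop("unsupported channel count: ", nch)
  }
  vals
}

#' Convert an RGB image to grayscale
#'
#' Per-pixel ITU-R BT.601 luminance `0.2989 R + 0.5870 G + 0.1140 B`,
#' rounded half-up to the nearest integer and clipped to `[0, 255]`.
#' Grayscale input is returned unchanged.
#'
#' @param img RGB array (height x width x 3) or grayscale matrix.
#' @param weights numeric(3) channel weights.
#' @return grayscale matrix of 8-bit integers.
#' @examples
#' rgb <- array(c(100, 150, 200), dim = c(1, 1, 3))
#' toGrayscale(rgb)  # 141
#' @export
toGrayscale <- function(img, weights = c(0.2989, 0.5870, 0.1140)) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L, dim(img)[3L] == 3L)
  g <- weights[1] * img[, , 1] + weights[2] * img[, , 2] +
       weights[3] * img[, , 3]
  pmin(pmax(floor(g + 0.5), 0), 255)  # round half-up
}

#' Write a grayscale image or binary mask
#'
#' Writes an 8-bit PNG or TIFF. Logical masks are written as 0/255.
#'
#' @param img grayscale matrix (values in `[0, 255]`) or logical mask.
#' @param path output path, extension selects the format.
#' @export
writeGrayImage <- function(img, path) {
  if (is.logical(img)) img <- img * 255
  x <- pmin(pmax(img, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(x, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(x, path)
  else stop("unsupported output format: ", ext)
  invisible(path)
}

#' Write a 16-bit label mask
#'
#' Writes an integer label image (0 = background) as a 16-bit grayscale
#' TIFF, preserving up to 65535 distinct labels.
#'
#' @param labels integer matrix of component labels.
#' @param path output `.tif`/`.tiff` path.
#' @export
writeLabelMask <- function(labels, path) {
  stopifnot(max(labels) <= 65535L)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label mask written by [writeLabelMask()]
#' @param path path to the label TIFF.
#' @return integer matrix of labels.
#' @export
readLabelMask <- function(path) {
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(raw)) raw <- raw[[1L]]
  raw
}

#' Write a feature/report table as CSV
#'
#' Writes a data frame with a header row, floating-point values at 6
#' significant digits, in the row order given (deterministic).
#'
#' @param rows data.frame; all rows share one schema.
#' @param path output path.
#' @export
writeFeatureTable <- function(rows, path) {
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
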