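#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' NucleusRegion: one segmented nucleus
#'
#' A single 8-connected component returned by [segmentNuclei()]: its binary
#' mask and masked grayscale crop (background pixels exactly 0), both cropped
#' to the bounding box, plus the bounding box in full-image coordinates and
#' the foreground pixel count.
#'
#' Coordinates are 0-based, row-major, `(row, col)` order with the origin at
#' the top-left pixel; the bounding box `c(row0, col0, row1, col1)` is
#' half-open (`row1`, `col1` exclusive).
#'
#' @slot label positive integer component label.
#' @slot bbox integer(4), half-open bounding box `c(row0, col0, row1, col1)`.
#' @slot mask logical matrix, the component mask cropped to `bbox`.
#' @slot pixels numeric matrix of 8-bit intensities; entries outside `mask`
#'   are exactly 0.
#' @slot area integer, number of foreground pixels.
#'
#' @seealso [segmentNuclei()], [nucleusFeatures()]
#' @export
setClass("NucleusRegion",
  representation(
    label  = "integer",
    bbox   = "integer",
    mask   = "matrix",
    pixels = "matrix",
    area   = "integer"
  )
)

setValidity("NucleusRegion", function(object) {
  msg <- NULL
  if (length(object@label) != 1L || object@label < 1L)
    msg <- c(msg, "'label' must be a single positive integer")
  if (length(object@bbox) != 4L)
    msg <- c(msg, "'bbox' must have length 4")
  if (!identical(dim(object@mask), dim(object@pixels)))
    msg <- c(msg, "'mask' and 'pixels' must have identical dimensions")
  if (!is.logical(object@mask))
    msg <- c(msg, "'mask' must be a logical matrix")
  if (any(object@pixels[!object@mask] != 0))
    msg <- c(msg, "pixels outside the mask must be exactly 0")
  if (object@area != sum(object@mask))
    msg <- c(msg, "'area' must equal the number of TRUE mask pixels")
  if (is.null(msg)) TRUE else msg
})

#' SegmentationParams: parameters of the nucleus segmentation chain
#'
#' Tunable parameters of the smoothing / Canny / morphology / size-filter
#' chain. Defaults reproduce the chain on synthetic H&E-like fields:
#' Gaussian sigma 2 px, automatic hysteresis thresholds (Otsu on gradient
#' magnitude, low = 0.4 * high), disk closing radius 3 px, and a minimum
#' component area of 500 px.
#'
#' @slot smoothingSigma numeric, Gaussian standard deviation in pixels.
#' @slot cannyLow,cannyHigh numeric fractions of the gradient-magnitude
#'   maximum, or `NA_real_` for automatic selection.
#' @slot closingRadius integer, disk radius of the morphological closing.
#' @slot minArea integer, minimum component area kept (pixels).
#' @slot smoothingMode `"gaussian"` (default) or `"log"` for a true
#'   Laplacian-of-Gaussian response rescaled back to `[0, 255]`.
#'
#' @export
setClass("SegmentationParams",
  representation(
    smoothingSigma = "numeric",
    cannyLow       = "numeric",
    cannyHigh      = "numeric",
    closingRadius  = "integer",
    minArea        = "integer",
    smoothingMode  = "character"
  ),
  prototype(
    smoothingSigma = 2.0,
    cannyLow       = NA_real_,
    cannyHigh      = NA_real_,
    closingRadius  = 3L,
    minArea        = 500L,
    smoothingMode  = "gaussian"
  )
)

setValidity("SegmentationParams", function(object) {
  msg <- NULL
  if (object@smoothingSigma <= 0)
    msg <- c(msg, "'smoothingSigma' must be > 0")
  if (object@minArea < 1L)
    msg <- c(msg, "'minArea' must be >= 1")
  if (object@closingRadius < 0L)
    msg <- c(msg, "'closingRadius' must be >= 0")
  if (!is.na(object@cannyLow) && !is.na(object@cannyHigh) &&
      object@cannyLow >= object@cannyHigh)
    msg <- c(msg, "'cannyLow' must be < 'cannyHigh'")
  if (!object@smoothingMode %in% c("gaussian", "log"))
    msg <- c(msg, "'smoothingMode' must be \"gaussian\" or \"log\"")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SegmentationParams-class Constructor.
#' @param smoothingSigma,cannyLow,cannyHigh,closingRadius,minArea,smoothingMode
#'   see slots.
#' @return A `SegmentationParams` object.
#' @examples
#' segmentationParams(minArea = 300)
#' @export
segmentationParams <- function(smoothingSigma = 2.0,
                               cannyLow = NA_real_, cannyHigh = NA_real_,
                               closingRadius = 3L, minArea = 500L,
                               smoothingMode = c("gaussian", "log")) {
  new("SegmentationParams",
      smoothingSigma = as.numeric(smoothingSigma),
      cannyLow = as.numeric(cannyLow), cannyHigh = as.numeric(cannyHigh),
      closingRadius = as.integer(closingRadius),
      minArea = as.integer(minArea),
      smoothingMode = match.arg(smoothingMode))
}

#' PatientProfile: per-patient mean feature vector
#'
#' The per-patient aggregate: the arithmetic mean, over all of a patient's
#' segmented nuclei (pooled across images), of each of the 63 features.
#' A feature is `NA` only if it was undefined for every nucleus.
#'
#' @slot patientId character scalar.
#' @slot group `"low"` or `"high"` CIN grade group.
#' @slot nImages integer, number of images contributing nuclei.
#' @slot nNuclei integer, number of nuclei pooled.
#' @slot means named numeric(63) in canonical feature order
#'   (see [featureNames63()]).
#' @export
setClass("PatientProfile",
  representation(
    patientId = "character",
    group     = "character",
    nImages   = "integer",
    nNuclei   = "integer",
    means     = "numeric"
  )
)

setValidity("PatientProfile", function(object) {
  msg <- NULL
  if (!object@group %in% c("low", "high"))
    msg <- c(msg, "'group' must be \"low\" or \"high\"")
  if (object@nNuclei < 1L)
    msg <- c(msg, "'nNuclei' must be >= 1")
  if (length(object@means) != 63L ||
      !identical(names(object@means), featureNames63()))
    msg <- c(msg, "'means' must be a named numeric(63) in canonical order")
  if (is.null(msg)) TRUE else msg
})

#' NuclearCohort: patients-by-features cohort container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' 63 x patients matrix of per-patient mean feature values (assay
#' `"features"`) and the per-patient annotation (`patient_id`, `group`,
#' `n_images`, `n_nuclei`) as `colData`. Rows follow the canonical feature
#' order of [featureNames63()]; columns are ordered by group then patient id.
#'
#' @seealso [buildCohort()], [compareGroups()]
#' @export
setClass("NuclearCohort", contains = "SummarizedExperiment")

setValidity("NuclearCohort", function(object) {
  msg <- NULL
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  if (!identical(rownames(object), featureNames63()))
    msg <- c(msg, "rownames must equal featureNames63()")
  cd <- SummarizedExperiment::colData(object)
  need <- c("patient_id", "group", "n_images", "n_nuclei")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(cd$patient_id))
      msg <- c(msg, "patient ids must be unique")
    if (!all(cd$group %in% c("low", "high")))
      msg <- c(msg, "group labels must be \"low\" or \"high\"")
  }
  if (is.null(msg)) TRUE else msg
})

#' ScreeningReport: per-feature two-group comparison table
#'
#' Result of [compareGroups()]: one row per feature (63 rows, alphabetical
#' by feature name) with the raw Wilcoxon rank-sum p-value, the
#' Benjamini-Hochberg adjusted p-value, the point-biserial correlation with
#' the group label (low = 0, high = 1), and per-group mean and standard
#' error.
#'
#' @slot table data.frame with columns `feature`, `p_raw`, `p_adj`, `r_pb`,
#'   `mean_low`, `se_low`, `mean_high`, `se_high`.
#' @slot alpha numeric significance level.
#' @slot mTests integer, number of tests used in the FDR correction.
#' @export
setClass("ScreeningReport",
  representation(table = "data.frame", alpha = "numeric", mTests = "integer")
)

setValidity("ScreeningReport", function(object) {
  need <- c("feature", "p_raw", "p_adj", "r_pb",
            "mean_low", "se_low", "mean_high", "se_high")
  if (!identical(colnames(object@table), need))
    return(paste("table columns must be:", paste(need, collapse = ", ")))
  TRUE
})

#' NucleusSpec: planted parameters of one synthetic nucleus
#'
#' Ground-truth parameters from which [makeNucleusMask()] and
#' [renderImage()] draw one synthetic nucleus: an ellipse of geometric mean
#' radius `baseRadius` and axis ratio `aspect`, radially perturbed by
#' harmonics 3-6 with relative amplitude `irregularityAmp`, filled with a
#' Gaussian random field of correlation length `textureCorrLen` around
#' `meanIntensity` with marginal standard deviation `intensitySd`.
#'
#' @slot center numeric(2), `(row, col)` center in pixels.
#' @slot baseRadius numeric, geometric mean radius in pixels (>= 14 so the
#'   area exceeds the 500 px size-filter threshold).
#' @slot aspect numeric >= 1, major/minor axis ratio.
#' @slot orientation numeric, radians.
#' @slot irregularityAmp numeric in `[0, 0.35]`, radial perturbation
#'   amplitude as a fraction of the radius.
#' @slot textureCorrLen numeric, correlation length of the interior texture
#'   field in pixels (coarseness proxy).
#' @slot meanIntensity,intensitySd numeric, 8-bit interior intensity mean
#'   and standard deviation (inhomogeneity proxy).
#' @export
setClass("NucleusSpec",
  representation(
    center          = "numeric",
    baseRadius      = "numeric",
    aspect          = "numeric",
    orientation     = "numeric",
    irregularityAmp = "numeric",
    textureCorrLen  = "numeric",
    meanIntensity   = "numeric",
    intensitySd     = "numeric"
  )
)

setValidity("NucleusSpec", function(object) {
  msg <- NULL
  if (length(object@center) != 2L)
    msg <- c(msg, "'center' must be (row, col)")
  if (object@baseRadius < 14)
    msg <- c(msg, "'baseRadius' must be >= 14 px (area >= 500 px)")
  if (object@aspect < 1)
    msg <- c(msg, "'aspect' must be >= 1")
  if (object@irregularityAmp < 0 || object@irregularityAmp > 0.35)
    msg <- c(msg, "'irregularityAmp' must be in [0, 0.35]")
  if (object@intensitySd < 0 || object@textureCorrLen <= 0)
    msg <- c(msg, "'intensitySd' must be >= 0 and 'textureCorrLen' > 0")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn NucleusSpec-class Constructor.
#' @param center,baseRadius,aspect,orientation,irregularityAmp see slots.
#' @param textureCorrLen,meanIntensity,intensitySd see slots.
#' @return A `NucleusSpec`.
#' @examples
#' nucleusSpec(center = c(40, 40), baseRadius = 16)
#' @export
nucleusSpec <- function(center, baseRadius, aspect = 1, orientation = 0,
                        irregularityAmp = 0, textureCorrLen = 3,
                        meanIntensity = 100, intensitySd = 10) {
  new("NucleusSpec", center = as.numeric(center),
      baseRadius = as.numeric(baseRadius), aspect = as.numeric(aspect),
      orientation = as.numeric(orientation),
      irregularityAmp = as.numeric(irregularityAmp),
      textureCorrLen = as.numeric(textureCorrLen),
      meanIntensity = as.numeric(meanIntensity),
      intensitySd = as.numeric(intensitySd))
}

#' GroupParams: sampling distributions for one patient group
#'
#' Distributions (mean, sd pairs) from which per-nucleus [NucleusSpec]
#' parameters are drawn, plus per-image layout and background parameters.
#' Two presets are provided by [groupParams()]: `"low_like"` and
#' `"high_like"`, where the high-grade-like preset has strictly larger means
#' of nucleus radius, boundary irregularity, texture correlation length, and
#' intensity inhomogeneity — the group-difference directions the screening
#' stage is expected to recover.
#'
#' @slot radiusMean,radiusSd nucleus base radius distribution (px).
#' @slot aspectMean,aspectSd axis-ratio distribution (truncated at 1).
#' @slot irregularityMean,irregularitySd radial perturbation amplitude
#'   distribution (truncated to `[0, 0.35]`).
#' @slot corrLenMean,corrLenSd texture correlation length distribution (px).
#' @slot intensityMean,intensityMeanSd interior mean-intensity distribution.
#' @slot intensitySdMean,intensitySdSd interior intensity-sd distribution.
#' @slot nucleiPerImage integer, nuclei planted per image.
#' @slot imagesPerPatient integer(2), images per patient alternate between
#'   these two counts (default 4 and 5).
#' @slot backgroundIntensity,backgroundNoiseSd background level and white
#'   noise sd (8-bit units).
#' @export
setClass("GroupParams",
  representation(
    radiusMean = "numeric", radiusSd = "numeric",
    aspectMean = "numeric", aspectSd = "numeric",
    irregularityMean = "numeric", irregularitySd = "numeric",
    corrLenMean = "numeric", corrLenSd = "numeric",
    intensityMean = "numeric", intensityMeanSd = "numeric",
    intensitySdMean = "numeric", intensitySdSd = "numeric",
    nucleiPerImage = "integer",
    imagesPerPatient = "integer",
    backgroundIntensity = "numeric", backgroundNoiseSd = "numeric"
  )
)

setValidity("GroupParams", function(object) {
  msg <- NULL
  if (any(c(object@radiusSd, object@aspectSd, object@irregularitySd,
            object@corrLenSd, object@intensityMeanSd, object@intensitySdSd,
            object@backgroundNoiseSd) < 0))
    msg <- c(msg, "all sd parameters must be >= 0")
  if (object@nucleiPerImage < 1L)
    msg <- c(msg, "'nucleiPerImage' must be >= 1")
  if (length(object@imagesPerPatient) != 2L || any(object@imagesPerPatient < 1L))
    msg <- c(msg, "'imagesPerPatient' must be two counts >= 1")
  if (is.null(msg)) TRUE else msg
})

#' CohortSpec: full synthetic-cohort description
#'
#' Everything needed to generate a reproducible two-group synthetic cohort:
#' group sizes, the per-group sampling presets, frame size and master seed.
#' Identical spec + seed yields bit-identical images, masks and manifests.
#'
#' @slot nPatientsPerGroup integer (default 22, the study-sized cohort).
#' @slot seed integer master seed.
#' @slot imageSize integer(2) `(height, width)` in pixels.
#' @slot lowParams,highParams [GroupParams] for the two groups.
#' @export
setClass("CohortSpec",
  representation(
    nPatientsPerGroup = "integer",
    seed      = "integer",
    imageSize = "integer",
    lowParams  = "GroupParams",
    highParams = "GroupParams"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- NULL
  if (object@nPatientsPerGroup < 1L)
    msg <- c(msg, "'nPatientsPerGroup' must be >= 1")
  if (length(object@imageSize) != 2L || any(object@imageSize < 64L))
    msg <- c(msg, "'imageSize' must be (height, width), both >= 64")
  if (is.null(msg)) TRUE else msg
})
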