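#' Canonical names of the 63 nuclear features
#'
#' The fixed, ordered naming of the 63 per-nucleus features: histogram
#' moments (1-4), co-occurrence (5-17), run-length (18-22), second-level
#' Daubechies-2 wavelet detail statistics in the horizontal, diagonal and
#' vertical directions (23-46), Tamura (47-52), local binary pattern
#' (53-54) and morphology (55-63). All feature vectors, cohort rows and
#' report tables in the package use these names in this order.
#'
#' @return character(63).
#' @examples
#' featureNames63()[c(20, 62)]  # gray_level_nonuniformity, nucleus_solidity
#' @export
featureNames63 <- function() {
  dwtStats <- c("mean_value", "median_value", "max_value", "min_value",
                "range_of_values", "standard_deviation",
                "median_absolute_deviation", "mean_absolute_deviation")
  c(
    "mean_value", "standard_deviation", "skewness", "kurtosis",
    "angular_second_moment", "contrast", "inverse_difference_moment",
    "entropy", "correlation", "sum_of_squares", "sum_average",
    "sum_entropy", "sum_variance", "difference_variance",
    "difference_entropy", "information_measure_correlation_1",
    "information_measure_correlation_2",
    "short_run_emphasis", "long_run_emphasis", "gray_level_nonuniformity",
    "run_length_nonuniformity", "run_percentage",
    paste0("dwt2h_", dwtStats),
    paste0("dwt2d_", dwtStats),
    paste0("dwt2v_", dwtStats),
    "tamura_coarseness_1", "tamura_coarseness_2", "tamura_coarseness_3",
    "tamura_coarseness_4", "tamura_contrast", "tamura_roughness",
    "local_binary_pattern_mean_value",
    "local_binary_pattern_standard_deviation",
    "nucleus_area", "nucleus_perimeter", "nucleus_equivalent_diameter",
    "nucleus_convex_area", "nucleus_major_axis_length",
    "nucleus_minor_axis_length", "nucleus_eccentricity",
    "nucleus_solidity", "nucleus_extent"
  )
}

#' @rdname NucleusRegion-class
#' @param object,x a `NucleusRegion`.
#' @export
setGeneric("regionArea", function(x) standardGeneric("regionArea"))
#' @rdname NucleusRegion-class
#' @export
setGeneric("regionMask", function(x) standardGeneric("regionMask"))
#' @rdname NucleusRegion-class
#' @export
setGeneric("regionPixels", function(x) standardGeneric("regionPixels"))
#' @rdname NucleusRegion-class
#' @export
setGeneric("regionBBox", function(x) standardGeneric("regionBBox"))
#' @rdname NucleusRegion-class
#' @export
setGeneric("regionLabel", function(x) standardGeneric("regionLabel"))

#' @rdname NucleusRegion-class
setMethod("regionArea", "NucleusRegion", function(x) x@area)
#' @rdname NucleusRegion-class
setMethod("regionMask", "NucleusRegion", function(x) x@mask)
#' @rdname NucleusRegion-class
setMethod("regionPixels", "NucleusRegion", function(x) x@pixels)
#' @rdname NucleusRegion-class
setMethod("regionBBox", "NucleusRegion", function(x) x@bbox)
#' @rdname NucleusRegion-class
setMethod("regionLabel", "NucleusRegion", function(x) x@label)

setMethod("show", "NucleusRegion", function(object) {
  bb <- object@bbox
  cat("NucleusRegion label", object@label,
      sprintf("| bbox [%d,%d)x[%d,%d) | area %d px\n",
              bb[1], bb[3], bb[2], bb[4], object@area))
})

setMethod("show", "SegmentationParams", function(object) {
  cat("SegmentationParams:\n")
  cat("  smoothing  :", object@smoothingMode,
      "sigma =", object@smoothingSigma, "\n")
  cat("  canny      :",
      if (is.na(object@cannyHigh)) "auto (Otsu, low = 0.4*high)"
      else paste0("low = ", object@cannyLow, ", high = ", object@cannyHigh),
      "\n")
  cat("  closing    : disk radius", object@closingRadius, "\n")
  cat("  min area   :", object@minArea, "px\n")
})

setMethod("show", "PatientProfile", function(object) {
  cat("PatientProfile", object@patientId,
      sprintf("(%s grade): %d nuclei from %d image(s), %d/63 features defined\n",
              object@group, object@nNuclei, object@nImages,
              sum(!is.na(object@means))))
})

setMethod("show", "NuclearCohort", function(object) {
  grp <- SummarizedExperiment::colData(object)$group
  cat("NuclearCohort:", ncol(object), "patients x", nrow(object),
      "features\n")
  cat("  groups: low =", sum(grp == "low"), ", high =", sum(grp == "high"),
      "\n")
  callNextMethod()
})

#' @rdname ScreeningReport-class
#' @param object,x a `ScreeningReport`.
#' @export
setGeneric("significantRaw", function(x) standardGeneric("significantRaw"))
#' @rdname ScreeningReport-class
#' @export
setGeneric("significantAdjusted",
           function(x) standardGeneric("significantAdjusted"))

#' @rdname ScreeningReport-class
setMethod("significantRaw", "ScreeningReport", function(x) {
  tab <- x@table
  tab$feature[!is.na(tab$p_raw) & tab$p_raw < x@alpha]
})
#' @rdname ScreeningReport-class
setMethod("significantAdjusted", "ScreeningReport", function(x) {
  tab <- x@table
  tab$feature[!is.na(tab$p_adj) & tab$p_adj < x@alpha]
})

setMethod("show", "ScreeningReport", function(object) {
  cat("ScreeningReport:", nrow(object@table), "features, alpha =",
      object@alpha, ", m =", object@mTests, "tests\n")
  cat("  raw p <", object@alpha, ":", length(significantRaw(object)),
      "features\n")
  cat("  FDR-adjusted p <", object@alpha, ":",
      length(significantAdjusted(object)), "features\n")
})

#' @rdname ScreeningReport-class
#' @param row.names,optional,... passed to [base::as.data.frame()].
#' @export
as.data.frame.ScreeningReport <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  x@table
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", 2L * object@nPatientsPerGroup, "patients (",
      object@nPatientsPerGroup, "per group ),",
      paste(object@imageSize, collapse = "x"), "px frames, seed",
      object@seed, "\n")
})
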