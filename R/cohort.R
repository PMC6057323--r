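# Aggregation of per-nucleus vectors to per-patient profiles and the
# two-group cohort container.

#' Per-patient mean feature vector
#'
#' Pools all of a patient's nuclei (across the patient's images) and takes
#' the per-feature arithmetic mean over defined values; a feature is `NA`
#' only when it was missing for every nucleus.
#'
#' @param vectors list of named numeric(63) per-nucleus vectors, or a
#'   nuclei x 63 matrix.
#' @param patientId character scalar.
#' @param group `"low"` or `"high"`.
#' @param nImages number of images the nuclei came from.
#' @return a [PatientProfile].
#' @export
patientMean <- function(vectors, patientId, group, nImages = 1L) {
  if (is.list(vectors)) {
    if (length(vectors) == 0L) stop("no nucleus vectors for patient ",
                                    patientId)
    vectors <- do.call(rbind, vectors)
  }
  if (nrow(vectors) == 0L) stop("no nucleus vectors for patient ", patientId)
  if (!identical(colnames(vectors), featureNames63()))
    stop("nucleus vectors must use the canonical 63-feature names")
  means <- colMeans(vectors, na.rm = TRUE)
  means[is.nan(means)] <- NA_real_
  new("PatientProfile", patientId = as.character(patientId),
      group = as.character(group), nImages = as.integer(nImages),
      nNuclei = nrow(vectors), means = means)
}

#' Assemble a two-group cohort table
#'
#' Builds a [NuclearCohort] (a `SummarizedExperiment`) from per-patient
#' profiles, ordered by group (`low` before `high`) then patient id.
#'
#' @param profiles list of [PatientProfile] objects with unique ids.
#' @return a [NuclearCohort].
#' @export
buildCohort <- function(profiles) {
  if (length(profiles) == 0L) stop("no patient profiles")
  ids <- vapply(profiles, function(p) p@patientId, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient ids: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  grp <- vapply(profiles, function(p) p@group, character(1))
  ord <- order(match(grp, c("low", "high")), ids)
  profiles <- profiles[ord]; ids <- ids[ord]; grp <- grp[ord]
  mat <- vapply(profiles, function(p) p@means, numeric(63L))
  rownames(mat) <- featureNames63()
  colnames(mat) <- ids
  cd <- S4Vectors::DataFrame(
    patient_id = ids,
    group = factor(grp, levels = c("low", "high")),
    n_images = vapply(profiles, function(p) p@nImages, integer(1)),
    n_nuclei = vapply(profiles, function(p) p@nNuclei, integer(1)),
    row.names = ids
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat), colData = cd)
  new("NuclearCohort", se)
}

#' Cohort feature matrix and group labels
#'
#' @param cohort a [NuclearCohort].
#' @return `cohortFeatures`: the 63 x patients matrix;
#'   `cohortGroups`: factor of group labels.
#' @export
cohortFeatures <- function(cohort) {
  SummarizedExperiment::assay(cohort, "features")
}

#' @rdname cohortFeatures
#' @export
cohortGroups <- function(cohort) {
  SummarizedExperiment::colData(cohort)$group
}
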