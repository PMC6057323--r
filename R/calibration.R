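# Type-I error calibration of the screening stage on null synthetic
# cohorts (both groups drawn from the same generator preset).

#' Type-I calibration on null cohorts
#'
#' Repeatedly generates cohorts in which both groups share the same
#' generator preset, runs the full pipeline, and records the fraction of
#' the 63 features with raw p < `alpha`. Under the null this fraction
#' should match the achievable size of the exact rank-sum test at the
#' chosen group size (0.0499 at 8 vs 8, essentially the nominal 0.05).
#'
#' The default replicate is deliberately small (8 + 8 patients, one
#' 160 x 160 image with 2 nuclei per patient): the calibration property
#' concerns the screening statistics, not image scale, and the reduced
#' frame keeps many replicates affordable.
#'
#' @param nReplicates number of null cohorts.
#' @param nPerGroup patients per group in each replicate.
#' @param imageSize frame size of the reduced-scale images.
#' @param nucleiPerImage,imagesPerPatient per-patient workload.
#' @param alpha significance level tallied.
#' @param seed master seed; replicate r uses `seed + 7919 * r`.
#' @return list with `fraction` (overall fraction of raw p < alpha),
#'   `perReplicate` (numeric vector), `nTests` (total test count).
#' @export
typeICalibration <- function(nReplicates = 200L, nPerGroup = 8L,
                             imageSize = c(160L, 160L),
                             nucleiPerImage = 2L, imagesPerPatient = 1L,
                             alpha = 0.05, seed = 1L) {
  gp <- groupParams("low_like", nucleiPerImage = as.integer(nucleiPerImage),
                    imagesPerPatient = rep(as.integer(imagesPerPatient), 2L))
  fr <- numeric(nReplicates)
  nSig <- 0L; nTot <- 0L
  for (r in seq_len(nReplicates)) {
    sp <- cohortSpec(nPatientsPerGroup = nPerGroup,
                     seed = (seed + 7919L * r) %% 2147483647L,
                     imageSize = imageSize,
                     lowParams = gp, highParams = gp)
    rep_ <- runPipeline(spec = sp)
    p <- as.data.frame(rep_)$p_raw
    p <- p[!is.na(p)]
    fr[r] <- mean(p < alpha)
    nSig <- nSig + sum(p < alpha)
    nTot <- nTot + length(p)
  }
  list(fraction = nSig / nTot, perReplicate = fr, nTests = nTot)
}
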