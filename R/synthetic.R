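# Seeded synthetic H&E-like cohort generator: fields of non-overlapping
# darkly-stained, radially-perturbed elliptical nuclei on a lighter noisy
# background, with two patient-group presets differing in nucleus size,
# boundary irregularity, texture coarseness and intensity inhomogeneity.

#' Group presets for the synthetic cohort
#'
#' `"low_like"` and `"high_like"` emulate the reported group-difference
#' directions: the high-grade-like preset has larger nuclei (base radius
#' mean 20 vs 16 px), more irregular boundaries (perturbation amplitude
#' 0.15 vs 0.05), coarser interior texture (correlation length 6 vs 3 px)
#' and stronger intensity inhomogeneity (sd 16 vs 10). Both share the
#' background (200 +/- 6) and the nucleus mean intensity (100).
#'
#' @param preset `"low_like"` or `"high_like"`.
#' @param ... named slot overrides (see [GroupParams-class]).
#' @return a [GroupParams].
#' @examples
#' groupParams("high_like", nucleiPerImage = 4L)
#' @export
groupParams <- function(preset = c("low_like", "high_like"), ...) {
  preset <- match.arg(preset)
  base <- list(
    radiusMean = 16, radiusSd = 1.2,
    aspectMean = 1.25, aspectSd = 0.12,
    irregularityMean = 0.05, irregularitySd = 0.02,
    corrLenMean = 3, corrLenSd = 0.4,
    intensityMean = 100, intensityMeanSd = 6,
    intensitySdMean = 10, intensitySdSd = 1.5,
    nucleiPerImage = 6L,
    imagesPerPatient = c(4L, 5L),
    backgroundIntensity = 200, backgroundNoiseSd = 6
  )
  if (preset == "high_like") {
    base$radiusMean <- 20
    base$radiusSd <- 1.8
    base$irregularityMean <- 0.15
    base$irregularitySd <- 0.04
    base$corrLenMean <- 6
    base$corrLenSd <- 0.8
    base$intensitySdMean <- 16
    base$intensitySdSd <- 2.5
  }
  over <- list(...)
  base[names(over)] <- over
  new("GroupParams",
      radiusMean = base$radiusMean, radiusSd = base$radiusSd,
      aspectMean = base$aspectMean, aspectSd = base$aspectSd,
      irregularityMean = base$irregularityMean,
      irregularitySd = base$irregularitySd,
      corrLenMean = base$corrLenMean, corrLenSd = base$corrLenSd,
      intensityMean = base$intensityMean,
      intensityMeanSd = base$intensityMeanSd,
      intensitySdMean = base$intensitySdMean,
      intensitySdSd = base$intensitySdSd,
      nucleiPerImage = as.integer(base$nucleiPerImage),
      imagesPerPatient = as.integer(base$imagesPerPatient),
      backgroundIntensity = base$backgroundIntensity,
      backgroundNoiseSd = base$backgroundNoiseSd)
}

#' Synthetic cohort description
#'
#' @param nPatientsPerGroup patients per group (default 22).
#' @param seed master seed; identical spec + seed gives bit-identical
#'   output.
#' @param imageSize `(height, width)` in pixels (default 512 x 512).
#' @param lowParams,highParams group presets (defaults
#'   `groupParams("low_like")` / `groupParams("high_like")`).
#' @return a [CohortSpec].
#' @export
cohortSpec <- function(nPatientsPerGroup = 22L, seed = 1L,
                       imageSize = c(512L, 512L),
                       lowParams = groupParams("low_like"),
                       highParams = groupParams("high_like")) {
  new("CohortSpec", nPatientsPerGroup = as.integer(nPatientsPerGroup),
      seed = as.integer(seed), imageSize = as.integer(imageSize),
      lowParams = lowParams, highParams = highParams)
}

#' Rasterize one synthetic nucleus mask
#'
#' A star-convex region: the ellipse of geometric mean radius `baseRadius`
#' and axis ratio `aspect`, radially modulated by harmonics 3-6,
#' `r(theta) = r_ell(theta) * (1 + amp * sum_h a_h cos(h theta + phi_h))`,
#' with `a_h` (normalized so `sum |a_h| = 1`, keeping the perturbation
#' bounded by `amp`) and `phi_h` drawn from the current RNG stream.
#'
#' @param spec a [NucleusSpec].
#' @param frame `(height, width)` of the target frame.
#' @return logical mask of size `frame` with one 8-connected component.
#' @export
makeNucleusMask <- function(spec, frame) {
  rmax <- spec@baseRadius * sqrt(spec@aspect) * (1 + spec@irregularityAmp)
  ctr <- spec@center
  if (ctr[1] - rmax < 2 || ctr[2] - rmax < 2 ||
      ctr[1] + rmax > frame[1] - 1 || ctr[2] + rmax > frame[2] - 1)
    stop("nucleus does not fit inside the frame with a 2 px margin")
  a_h <- runif(4L, -1, 1)
  a_h <- a_h / sum(abs(a_h))
  phi <- runif(4L, 0, 2 * pi)

  r0 <- max(1L, floor(ctr[1] - rmax - 1)); r1 <- min(frame[1], ceiling(ctr[1] + rmax + 1))
  c0 <- max(1L, floor(ctr[2] - rmax - 1)); c1 <- min(frame[2], ceiling(ctr[2] + rmax + 1))
  rr <- outer(r0:r1 - ctr[1], rep(1, c1 - c0 + 1L))
  cc <- outer(rep(1, r1 - r0 + 1L), c0:c1 - ctr[2])
  theta <- atan2(rr, cc)
  dist <- sqrt(rr^2 + cc^2)
  # ellipse radius at angle theta relative to orientation
  amaj <- spec@baseRadius * sqrt(spec@aspect)
  amin <- spec@baseRadius / sqrt(spec@aspect)
  trel <- theta - spec@orientation
  rell <- (amaj * amin) / sqrt((amin * cos(trel))^2 + (amaj * sin(trel))^2)
  pert <- 1 + spec@irregularityAmp *
    (a_h[1] * cos(3 * theta + phi[1]) + a_h[2] * cos(4 * theta + phi[2]) +
     a_h[3] * cos(5 * theta + phi[3]) + a_h[4] * cos(6 * theta + phi[4]))
  sub <- dist <= rell * pert
  mask <- matrix(FALSE, frame[1], frame[2])
  mask[r0:r1, c0:c1] <- sub
  mask
}

# Draw one NucleusSpec from a GroupParams at a given center.
drawNucleusSpec <- function(group, center) {
  nucleusSpec(
    center = center,
    baseRadius = max(14, rnorm(1, group@radiusMean, group@radiusSd)),
    aspect = max(1, rnorm(1, group@aspectMean, group@aspectSd)),
    orientation = runif(1, 0, pi),
    irregularityAmp = min(0.35, max(0, rnorm(1, group@irregularityMean,
                                             group@irregularitySd))),
    textureCorrLen = max(0.5, rnorm(1, group@corrLenMean, group@corrLenSd)),
    meanIntensity = max(20, min(180, rnorm(1, group@intensityMean,
                                           group@intensityMeanSd))),
    intensitySd = max(0, rnorm(1, group@intensitySdMean,
                               group@intensitySdSd))
  )
}

# Dart-throwing placement of nucleus centers with >= 4 px gaps between
# outer envelopes and an 8 px border margin (so planted nuclei never touch
# the frame border and survive the border filter).
placeNuclei <- function(group, frame, nNuclei) {
  margin <- 8
  specs <- list()
  radii <- numeric(0)
  tries <- 0L
  while (length(specs) < nNuclei && tries < 4000L) {
    tries <- tries + 1L
    r <- max(14, rnorm(1, group@radiusMean, group@radiusSd))
    rmax <- r * sqrt(group@aspectMean + 3 * group@aspectSd) * 1.35
    lo1 <- margin + rmax; hi1 <- frame[1] - margin - rmax
    lo2 <- margin + rmax; hi2 <- frame[2] - margin - rmax
    if (hi1 <= lo1 || hi2 <= lo2)
      stop("frame too small for the requested nuclei")
    ctr <- c(runif(1, lo1, hi1), runif(1, lo2, hi2))
    ok <- TRUE
    for (k in seq_along(specs)) {
      prev <- specs[[k]]
      if (sqrt(sum((prev@center - ctr)^2)) <
          radii[k] + rmax + 4) { ok <- FALSE; break }
    }
    if (!ok) next
    sp <- drawNucleusSpec(group, ctr)
    sp@baseRadius <- r
    specs[[length(specs) + 1L]] <- sp
    radii <- c(radii, rmax)
  }
  if (length(specs) < nNuclei)
    stop("nucleus placement failed; reduce 'nucleiPerImage' or enlarge ",
         "the frame")
  specs
}

# Gaussian random field with correlation length L: white noise smoothed
# with a Gaussian kernel of sigma = L/2, standardized to unit sd.
gaussianField <- function(nr, nc, corrLen) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  sig <- max(corrLen / 2, 0.3)
  sm <- smoothField(z, sig)
  s <- sd(as.numeric(sm))
  if (s == 0) sm else sm / s
}

# Gaussian smoothing without the [0,255] clipping of smoothImage().
smoothField <- function(m, sigma) {
  k <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-k:k)^2) / (2 * sigma^2))
  kern <- outer(g, g); kern <- kern / sum(kern)
  convolveReflect(m, kern)
}

#' Render one synthetic microscopy image
#'
#' Background = `backgroundIntensity` + white noise; each nucleus is filled
#' with `meanIntensity` plus a Gaussian random field of correlation length
#' `textureCorrLen` scaled to `intensitySd`, and composited over the
#' background through a 2 px smoothed boundary transition. The label mask
#' gives the planted ground truth per nucleus.
#'
#' @param specs list of [NucleusSpec] (pairwise non-overlapping).
#' @param group a [GroupParams] (background parameters).
#' @param frame `(height, width)` in pixels.
#' @param seed integer seed for this image's randomness.
#' @return list with `image` (8-bit grayscale matrix) and `labels`
#'   (integer matrix, 0 = background).
#' @export
renderImage <- function(specs, group, frame, seed) {
  set.seed(seed)
  img <- group@backgroundIntensity +
    matrix(rnorm(prod(frame), 0, group@backgroundNoiseSd), frame[1], frame[2])
  labels <- matrix(0L, frame[1], frame[2])
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    mask <- makeNucleusMask(sp, frame)
    labels[mask] <- i
    # work on an inflated bounding box; the alpha transition dies out well
    # within 6 px of the mask
    idx <- which(mask, arr.ind = TRUE)
    r0 <- max(1L, min(idx[, 1]) - 6L); r1 <- min(frame[1], max(idx[, 1]) + 6L)
    c0 <- max(1L, min(idx[, 2]) - 6L); c1 <- min(frame[2], max(idx[, 2]) + 6L)
    mcrop <- mask[r0:r1, c0:c1, drop = FALSE]
    tex <- gaussianField(nrow(mcrop), ncol(mcrop), sp@textureCorrLen)
    nucVals <- sp@meanIntensity + sp@intensitySd * tex
    alpha <- smoothField(mcrop * 1, 1)   # ~2 px boundary transition
    alpha[alpha < 0.02] <- 0
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] * (1 - alpha) + nucVals * alpha
  }
  list(image = pmin(pmax(round(img), 0), 255), labels = labels)
}

# Deterministic per-image sub-seed from the cohort master seed.
imageSeed <- function(seed, patientIndex, imageIndex) {
  (seed * 97L + patientIndex * 1009L + imageIndex * 31L) %% 2147483647L
}

#' Simulate a synthetic cohort in memory
#'
#' Generates every image of the cohort described by `spec` without touching
#' the disk. Patients alternate between the two per-patient image counts
#' (default 4 and 5 images).
#'
#' @param spec a [CohortSpec].
#' @return list with `images` (list of records: `patient_id`, `group`,
#'   `image_index`, `image`, `labels`, `specs`) and `manifest`
#'   (data.frame patient_id, image_index, group).
#' @seealso [generateCohort()] for the on-disk variant.
#' @export
simulateCohort <- function(spec) {
  records <- list()
  manifest <- list()
  pGlobal <- 0L
  for (g in c("low", "high")) {
    gp <- if (g == "low") spec@lowParams else spec@highParams
    for (p in seq_len(spec@nPatientsPerGroup)) {
      pGlobal <- pGlobal + 1L
      pid <- sprintf("%s_%02d", g, p)
      nImg <- gp@imagesPerPatient[(p - 1L) %% 2L + 1L]
      for (im in seq_len(nImg)) {
        sd_ <- imageSeed(spec@seed, pGlobal, im)
        set.seed(sd_)
        specs <- placeNuclei(gp, spec@imageSize, gp@nucleiPerImage)
        out <- renderImage(specs, gp, spec@imageSize, seed = sd_ + 1L)
        records[[length(records) + 1L]] <-
          list(patient_id = pid, group = g, image_index = im,
               image = out$image, labels = out$labels, specs = specs)
        manifest[[length(manifest) + 1L]] <-
          data.frame(patient_id = pid, image_index = im, group = g)
      }
    }
  }
  list(images = records, manifest = do.call(rbind, manifest))
}

#' Generate a synthetic cohort on disk
#'
#' Writes, under `dir`: one 8-bit PNG per image, one 16-bit TIFF label mask
#' per image, `manifest.csv` (patient_id, image_path, group) and
#' `ground_truth.csv` (per-nucleus planted parameters). Fully determined by
#' the spec seed.
#'
#' @param spec a [CohortSpec].
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
generateCohort <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulateCohort(spec)
  manifest <- list(); truth <- list()
  for (rec in sim$images) {
    stem <- sprintf("%s_img%d", rec$patient_id, rec$image_index)
    imgPath <- file.path(dir, paste0(stem, ".png"))
    writeGrayImage(rec$image, imgPath)
    writeLabelMask(rec$labels, file.path(dir, paste0(stem, "_labels.tif")))
    manifest[[length(manifest) + 1L]] <-
      data.frame(patient_id = rec$patient_id,
                 image_path = paste0(stem, ".png"), group = rec$group)
    for (i in seq_along(rec$specs)) {
      sp <- rec$specs[[i]]
      truth[[length(truth) + 1L]] <- data.frame(
        patient_id = rec$patient_id, image_index = rec$image_index,
        nucleus = i, center_row = sp@center[1], center_col = sp@center[2],
        base_radius = sp@baseRadius, aspect = sp@aspect,
        irregularity_amp = sp@irregularityAmp,
        texture_corr_len = sp@textureCorrLen,
        mean_intensity = sp@meanIntensity, intensity_sd = sp@intensitySd)
    }
  }
  manifest <- do.call(rbind, manifest)
  writeFeatureTable(manifest, file.path(dir, "manifest.csv"))
  writeFeatureTable(do.call(rbind, truth), file.path(dir, "ground_truth.csv"))
  invisible(manifest)
}
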