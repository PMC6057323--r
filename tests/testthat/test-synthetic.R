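test_that("nucleus masks are star-convex single components with the planted size", {
  set.seed(1)
  sp <- nucleusSpec(center = c(50, 50), baseRadius = 16)
  m <- makeNucleusMask(sp, c(100, 100))
  expect_equal(max(nucmorph:::labelComponents(m)), 1L)
  expect_equal(sum(m), pi * 16^2, tolerance = 0.05 * pi * 16^2)
  # smooth circular target: high solidity
  expect_gt(morphologyVector(m)[["nucleus_solidity"]], 0.98)
  # irregular target of the same radius: lower solidity
  set.seed(1)
  spIrr <- nucleusSpec(center = c(50, 50), baseRadius = 16,
                       irregularityAmp = 0.3)
  mIrr <- makeNucleusMask(spIrr, c(100, 100))
  expect_lt(morphologyVector(mIrr)[["nucleus_solidity"]],
            morphologyVector(m)[["nucleus_solidity"]])
  # determinism: same spec + seed, same mask
  set.seed(7); m1 <- makeNucleusMask(spIrr, c(100, 100))
  set.seed(7); m2 <- makeNucleusMask(spIrr, c(100, 100))
  expect_identical(m1, m2)
  # out-of-frame spec rejected
  expect_error(makeNucleusMask(nucleusSpec(center = c(5, 50),
                                           baseRadius = 16), c(100, 100)),
               "frame")
})

test_that("rendered fields recover planted nuclei with close centroids", {
  gp <- groupParams("low_like")
  set.seed(21)
  specs <- nucmorph:::placeNuclei(gp, c(320L, 320L), 5L)
  out <- renderImage(specs, gp, c(320L, 320L), seed = 22L)
  regs <- segmentNuclei(out$image)
  expect_length(regs, 5L)
  planted <- t(vapply(specs, function(s) s@center, numeric(2)))
  found <- t(vapply(regs, function(r) {
    idx <- which(regionMask(r), arr.ind = TRUE)
    regionBBox(r)[1:2] + c(mean(idx[, 1]), mean(idx[, 2]))
  }, numeric(2)))
  for (i in seq_len(nrow(planted))) {
    dists <- sqrt(rowSums((found - matrix(planted[i, ], nrow(found), 2,
                                          byrow = TRUE))^2))
    expect_lte(min(dists), 3)
  }
  # empty spec list -> pure background, nothing segmented
  bg <- renderImage(list(), gp, c(128L, 128L), seed = 5L)
  expect_length(segmentNuclei(bg$image), 0L)
})

test_that("cohort simulation is seed-deterministic with the declared layout", {
  sp <- cohortSpec(nPatientsPerGroup = 2L, seed = 11L,
                   imageSize = c(192L, 192L),
                   lowParams = groupParams("low_like", nucleiPerImage = 2L),
                   highParams = groupParams("high_like", nucleiPerImage = 2L))
  sim1 <- simulateCohort(sp)
  sim2 <- simulateCohort(sp)
  expect_identical(sim1$manifest, sim2$manifest)
  expect_identical(sim1$images[[3]]$image, sim2$images[[3]]$image)
  # 2 patients per group, alternating 4/5 images
  expect_equal(length(unique(sim1$manifest$patient_id)), 4L)
  counts <- table(sim1$manifest$patient_id)
  expect_setequal(as.integer(counts), c(4L, 5L))
})

test_that("on-disk cohorts carry images, masks, manifest and ground truth", {
  dir <- file.path(tempdir(), "cohtest")
  sp <- cohortSpec(nPatientsPerGroup = 1L, seed = 2L,
                   imageSize = c(192L, 192L),
                   lowParams = groupParams("low_like", nucleiPerImage = 2L,
                                           imagesPerPatient = c(1L, 1L)),
                   highParams = groupParams("high_like", nucleiPerImage = 2L,
                                            imagesPerPatient = c(1L, 1L)))
  man <- generateCohort(sp, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  expect_equal(nrow(man), 2L)
  img <- readMicroscopyImage(file.path(dir, man$image_path[1]))
  expect_equal(dim(img), c(192L, 192L))
  lab <- readLabelMask(file.path(dir, sub("\\.png$", "_labels.tif",
                                          man$image_path[1])))
  expect_equal(max(lab), 2L)
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), 4L)
  expect_true(all(gt$base_radius >= 14))
  unlink(dir, recursive = TRUE)
})

test_that("measured nucleus area tracks the planted radius", {
  gp <- groupParams("low_like", radiusSd = 3)
  areas <- c(); planted <- c()
  for (s in 1:8) {
    set.seed(100 + s)
    specs <- nucmorph:::placeNuclei(gp, c(256L, 256L), 3L)
    out <- renderImage(specs, gp, c(256L, 256L), seed = 200 + s)
    regs <- segmentNuclei(out$image)
    if (length(regs) != 3L) next
    found <- t(vapply(regs, function(r) {
      idx <- which(regionMask(r), arr.ind = TRUE)
      regionBBox(r)[1:2] + c(mean(idx[, 1]), mean(idx[, 2]))
    }, numeric(2)))
    for (i in seq_along(specs)) {
      d <- sqrt(rowSums((found - matrix(specs[[i]]@center, nrow(found), 2,
                                        byrow = TRUE))^2))
      j <- which.min(d)
      if (d[j] <= 3) {
        areas <- c(areas, regionArea(regs[[j]]))
        planted <- c(planted, pi * specs[[i]]@baseRadius^2)
      }
    }
  }
  expect_gte(length(areas), 15L)
  expect_gt(cor(areas, planted, method = "spearman"), 0.9)
})

test_that("doubling the texture correlation length raises measured coarseness", {
  mean_crs <- function(corrLen, seeds) {
    vals <- c()
    for (s in seeds) {
      set.seed(s)
      sp <- nucleusSpec(center = c(40, 40), baseRadius = 16,
                        textureCorrLen = corrLen, intensitySd = 14)
      gp <- groupParams("low_like")
      out <- renderImage(list(sp), gp, c(80L, 80L), seed = s)
      regs <- segmentNuclei(out$image)
      if (length(regs) != 1L) next
      vals <- c(vals, tamuraFeatures(regs[[1]])[["tamura_coarseness_1"]])
    }
    mean(vals)
  }
  expect_gt(mean_crs(8, 1:10), mean_crs(2, 1:10))
})
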