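# Unit and property tests for the six texture families. Small oracle
# samples run here; the 50-patch oracle-equivalence sweep lives in the
# acceptance suite.

test_that("histogram features use population moments over in-mask pixels", {
  r <- makeRegion(matrix(c(1, 2, 3), 1, 3))
  h <- histogramFeatures(r)
  expect_equal(as.numeric(h), c(2, sqrt(2 / 3), 0, 1.5), tolerance = 1e-12)
  # constant region: sd 0, higher moments undefined
  hc <- histogramFeatures(makeRegion(matrix(9, 4, 4)))
  expect_equal(as.numeric(hc[1:2]), c(9, 0))
  expect_true(all(is.na(hc[3:4])))
  # {0,0,0,255}
  expect_equal(histogramFeatures(makeRegion(matrix(c(0, 0, 0, 255), 2, 2)))[["mean_value"]],
               63.75)
  # mask excludes background zeros
  px <- matrix(0, 4, 4); mk <- matrix(FALSE, 4, 4)
  px[2, 2:3] <- c(10, 20); mk[2, 2:3] <- TRUE
  expect_equal(histogramFeatures(makeRegion(px, mk))[["mean_value"]], 15)
})

test_that("GLCM is a symmetric probability matrix honoring the mask", {
  p <- randomPatch(11)
  G <- glcm(p$region)
  expect_equal(sum(G), 1, tolerance = 1e-9)
  expect_equal(G, t(G), tolerance = 1e-12)
  expect_true(all(G >= 0))
  # constant patch: all mass on one diagonal cell
  Gc <- glcm(makeRegion(matrix(40, 6, 6)))
  expect_equal(max(diag(Gc)), 1)
  # two-column patch [[0,255],[0,255]]: horizontal pairs cross levels,
  # vertical pairs stay within level
  patch <- matrix(c(0, 0, 255, 255), 2, 2)
  G0 <- glcm(makeRegion(patch), directions = "deg0")
  expect_equal(G0[1, 16] + G0[16, 1], 1)
  G90 <- glcm(makeRegion(patch), directions = "deg90")
  expect_equal(G90[1, 1] + G90[16, 16], 1)
  # removing one pixel removes exactly the pairs incident to it
  p3 <- matrix(sample(0:255, 9), 3, 3)
  mkAll <- matrix(TRUE, 3, 3)
  mkHole <- mkAll; mkHole[2, 2] <- FALSE
  expect_equal(glcm(makeRegion(p3, mkHole)), oracleGLCM(p3, mkHole),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GLCM features match analytic values on degenerate patches", {
  f <- glcmFeatures(glcm(makeRegion(matrix(100, 8, 8))))
  expect_equal(f[["angular_second_moment"]], 1)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["inverse_difference_moment"]], 1)
  # checkerboard at 0 degrees, levels 1 and 16: CON = 15^2
  cb <- matrix(0, 8, 8); cb[(row(cb) + col(cb)) %% 2 == 1] <- 255
  expect_equal(glcmFeatures(glcm(makeRegion(cb), directions = "deg0"))[["contrast"]],
               225)
})

test_that("run-length features match direct evaluation on constant and distinct patches", {
  r44 <- makeRegion(matrix(77, 4, 4))
  f0 <- rlmFeatures(r44, directions = "deg0")
  expect_equal(as.numeric(f0), c(1 / 16, 16, 4, 4, 0.25), tolerance = 1e-12)
  # all-distinct levels: every run has length 1
  lv <- matrix(seq(0, 255, length.out = 16), 4, 4)
  f1 <- rlmFeatures(makeRegion(round(lv)))
  expect_equal(f1[["short_run_emphasis"]], 1)
  expect_equal(f1[["long_run_emphasis"]], 1)
  expect_equal(f1[["run_percentage"]], 1)
})

test_that("wavelet details annihilate constants and localize oriented structure", {
  w <- waveletFeatures(makeRegion(matrix(123, 16, 16)))
  expect_true(all(abs(w) < 1e-9))
  # range identity on a random patch
  p <- randomPatch(5)
  wp <- waveletFeatures(p$region)
  for (d in c("dwt2h", "dwt2d", "dwt2v")) {
    expect_equal(wp[[paste0(d, "_range_of_values")]],
                 wp[[paste0(d, "_max_value")]] - wp[[paste0(d, "_min_value")]])
  }
  # horizontal band -> horizontal detail dominates vertical
  hb <- rbind(matrix(200, 8, 16), matrix(50, 8, 16))
  wh <- waveletFeatures(makeRegion(hb))
  expect_gt(wh[["dwt2h_mean_absolute_deviation"]],
            wh[["dwt2v_mean_absolute_deviation"]])
  # sub-8x8 crop -> all undefined
  tiny <- waveletFeatures(makeRegion(matrix(9, 5, 7)))
  expect_true(all(is.na(tiny)))
})

test_that("Tamura coarseness grows with texel size and histogram sums to 100", {
  tc <- tamuraFeatures(makeRegion(matrix(50, 12, 12)))
  expect_equal(tc[["tamura_coarseness_1"]], 1)
  expect_equal(tc[["tamura_contrast"]], 0)
  expect_equal(tc[["tamura_roughness"]], 1)
  # fine checkerboard vs 16-px blocks
  n <- 32
  fine <- 127 + 100 * ((row(matrix(0, n, n)) + col(matrix(0, n, n))) %% 2 * 2 - 1)
  blocks <- 127 + 100 * ((((row(matrix(0, n, n)) - 1) %/% 16 +
                           (col(matrix(0, n, n)) - 1) %/% 16) %% 2) * 2 - 1)
  cFine <- tamuraFeatures(makeRegion(fine))[["tamura_coarseness_1"]]
  cBlocks <- tamuraFeatures(makeRegion(blocks))[["tamura_coarseness_1"]]
  expect_lt(cFine, cBlocks)
  p <- randomPatch(7)
  tp <- tamuraFeatures(p$region)
  expect_equal(sum(tp[c("tamura_coarseness_2", "tamura_coarseness_3",
                        "tamura_coarseness_4")]), 100, tolerance = 1e-9)
})

test_that("LBP codes follow the printed sign convention", {
  lc <- lbpFeatures(makeRegion(matrix(50, 8, 8)))
  expect_equal(as.numeric(lc), c(255, 0))   # s(0) = 1 for every neighbor
  # bright center among dark neighbors -> code 0 at the center
  m <- matrix(10, 5, 5); m[3, 3] <- 200
  codes <- oracleLBP(m, matrix(TRUE, 5, 5))
  centerOnly <- oracleLBP(m, {
    mk <- matrix(FALSE, 5, 5); mk[3, 3] <- TRUE; mk
  })
  expect_equal(centerOnly[1], 0)
  expect_equal(as.numeric(lbpFeatures(makeRegion(m))), codes,
               tolerance = 1e-9)
})

test_that("texture families agree with brute-force oracles on random masked patches", {
  for (s in 1:6) {
    p <- randomPatch(s)
    expect_equal(as.numeric(glcmFeatures(glcm(p$region))),
                 oracleGLCMFeatures(oracleGLCM(p$px, p$mk)),
                 tolerance = 1e-9)
    expect_equal(as.numeric(rlmFeatures(p$region)),
                 as.numeric(oracleRLM(p$px, p$mk)), tolerance = 1e-9)
    expect_equal(as.numeric(lbpFeatures(p$region)),
                 oracleLBP(p$px, p$mk), tolerance = 1e-9)
    expect_equal(as.numeric(waveletFeatures(p$region)),
                 oracleWaveletStats(p$px), tolerance = 1e-6)
    expect_equal(as.numeric(tamuraFeatures(p$region)),
                 oracleTamura(p$px, p$mk), tolerance = 1e-6)
  }
})

test_that("the texture vector is deterministic, named, and 180-degree symmetric", {
  p <- randomPatch(21)
  v1 <- textureVector(p$region)
  v2 <- textureVector(p$region)
  expect_identical(v1, v2)
  expect_identical(names(v1), featureNames63()[1:54])
  # GLCM/RLM families are invariant under 180-degree rotation
  rot <- makeRegion(p$px[nrow(p$px):1, ncol(p$px):1],
                    p$mk[nrow(p$mk):1, ncol(p$mk):1])
  expect_equal(glcmFeatures(glcm(rot)), glcmFeatures(glcm(p$region)),
               tolerance = 1e-9)
  expect_equal(rlmFeatures(rot), rlmFeatures(p$region), tolerance = 1e-9)
})

test_that("texture features are invariant to translation within a larger frame", {
  p <- randomPatch(31)
  big <- matrix(0, 30, 30); bigMk <- matrix(FALSE, 30, 30)
  big[8:23, 10:25] <- p$px; bigMk[8:23, 10:25] <- p$mk
  # same crop content, different position: extract back via the bbox
  shifted <- makeRegion(big[8:23, 10:25], bigMk[8:23, 10:25])
  expect_equal(textureVector(shifted), textureVector(p$region))
})

test_that("GLCM invariants hold across random patches", {
  for (s in c(3, 13, 23)) {
    p <- randomPatch(s)
    f <- glcmFeatures(glcm(p$region))
    expect_gte(f[["entropy"]], 0)
    expect_true(f[["angular_second_moment"]] >= 0 &&
                f[["angular_second_moment"]] <= 1)
    expect_lte(f[["inverse_difference_moment"]], 1)
    r <- rlmFeatures(p$region)
    expect_true(r[["run_percentage"]] > 0 && r[["run_percentage"]] <= 1)
    expect_lte(r[["short_run_emphasis"]], 1)
    expect_gte(r[["long_run_emphasis"]], 1)
  }
})
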