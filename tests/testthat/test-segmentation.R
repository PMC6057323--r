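test_that("smoothing preserves constants and reduces variance of structure", {
  const <- matrix(120, 20, 20)
  expect_equal(smoothImage(const, sigma = 2), const, tolerance = 1e-10,
               ignore_attr = TRUE)
  # single bright pixel: maximum response at that pixel
  spike <- matrix(0, 21, 21); spike[11, 11] <- 255
  sm <- smoothImage(spike, sigma = 2)
  expect_equal(which.max(sm), which.max(spike))
  expect_true(sm[11, 12] > sm[11, 15])  # radially decreasing
  # checkerboard variance shrinks
  cb <- matrix(0, 20, 20); cb[(row(cb) + col(cb)) %% 2 == 1] <- 255
  expect_lt(var(as.numeric(smoothImage(cb, 2))), var(as.numeric(cb)))
  expect_error(smoothImage(const, sigma = 0), "positive")
})

test_that("Canny finds no edges in constants, a line at a step, a ring around a disk", {
  expect_false(any(detectEdges(matrix(77, 30, 30))))
  # vertical step -> roughly one vertical line of edge pixels
  step <- cbind(matrix(50, 30, 15), matrix(200, 30, 15))
  ed <- detectEdges(smoothImage(step, 1.5))
  cols <- unique(which(ed, arr.ind = TRUE)[, 2])
  expect_true(length(cols) <= 3 && all(abs(cols - 15.5) < 3))
  # disk -> closed ring: complement has 2 components (inside + outside)
  img <- diskField(c(80L, 80L), list(c(40, 40)), radius = 15)
  ring <- detectEdges(smoothImage(img, 2))
  comp <- EBImage::bwlabel((!ring) * 1)
  expect_gte(max(comp), 2)
  inside <- comp[40, 40]; outside <- comp[2, 2]
  expect_true(inside != outside)  # ring separates center from frame
})

test_that("closing and filling turns rings into solid blobs and bridges small gaps", {
  expect_false(any(closeAndFill(matrix(FALSE, 20, 20), 3)))
  # closed ring -> filled disk
  n <- 41; ring <- abs(sqrt((row(matrix(0, n, n)) - 21)^2 +
                            (col(matrix(0, n, n)) - 21)^2) - 12) < 0.8
  filled <- closeAndFill(ring, 0)
  expect_true(filled[21, 21])
  expect_gt(sum(filled), pi * 11^2)
  # ring with a 2-px gap, closing radius 3 -> still filled
  gapRing <- ring
  gapRing[20:21, 32:34] <- FALSE
  filledGap <- closeAndFill(gapRing, 3)
  expect_true(filledGap[21, 21])
  expect_gt(sum(filledGap), pi * 10^2)
})

test_that("size filter enforces the 500-px threshold and drops border components", {
  big <- diskMask(64, 15, c(32, 32))       # area ~707
  expect_true(any(sizeFilter(big, 500)))
  small <- diskMask(64, 10, c(32, 32))     # area ~314
  expect_false(any(sizeFilter(small, 500)))
  expect_false(any(sizeFilter(matrix(FALSE, 10, 10), 500)))
  border <- diskMask(64, 15, c(5, 32))     # clipped by the frame border
  expect_false(any(sizeFilter(border, 100)))
  expect_true(any(sizeFilter(border, 100, discardBorder = FALSE)))
})

test_that("masking keeps values exactly on the mask support", {
  g <- matrix(sample(1:255, 64, replace = TRUE), 8, 8)
  expect_equal(applyMask(g, matrix(TRUE, 8, 8)), g)
  expect_true(all(applyMask(g, matrix(FALSE, 8, 8)) == 0))
  mk <- matrix(rep(c(TRUE, FALSE), each = 32), 8, 8)
  out <- applyMask(g, mk)
  expect_true(all((out != 0) == mk))
  expect_error(applyMask(g, matrix(TRUE, 4, 4)), "shape")
})

test_that("the full chain recovers planted disks, rejects sub-threshold ones", {
  centers <- list(c(60, 60), c(60, 200), c(160, 120), c(240, 60),
                  c(230, 230))
  img <- diskField(c(300L, 300L), centers, radius = 15)
  regs <- segmentNuclei(img)
  expect_length(regs, 5L)
  expect_true(all(vapply(regs, regionArea, integer(1)) >= 500L))
  # region masks pairwise disjoint by construction: bboxes hold one comp each
  for (r in regs) {
    expect_equal(max(nucmorph:::labelComponents(regionMask(r))), 1L)
    expect_true(all(regionPixels(r)[!regionMask(r)] == 0))
  }
  # adding a radius-10 disk (area < 500) leaves the count unchanged
  img2 <- img
  d <- sqrt((row(img2) - 90)^2 + (col(img2) - 260)^2)
  img2[d <= 10] <- 80
  expect_length(segmentNuclei(img2), 5L)
  # blank image -> empty list
  expect_length(segmentNuclei(matrix(128, 100, 100)), 0L)
})

test_that("segmentation is invariant under whole-pixel translation", {
  img <- diskField(c(120L, 120L), list(c(50, 50)), radius = 16)
  imgT <- diskField(c(120L, 120L), list(c(57, 61)), radius = 16)
  r1 <- segmentNuclei(img); r2 <- segmentNuclei(imgT)
  expect_length(r1, 1L); expect_length(r2, 1L)
  expect_equal(regionBBox(r2[[1]]) - regionBBox(r1[[1]]),
               c(7L, 11L, 7L, 11L), ignore_attr = TRUE)
  expect_equal(regionMask(r2[[1]]), regionMask(r1[[1]]))
})

test_that("8-connected labeling merges diagonal touches", {
  m <- matrix(FALSE, 5, 5); m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[4, 4] <- TRUE
  lab <- nucmorph:::labelComponents(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[1, 1], lab[2, 2])
})
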