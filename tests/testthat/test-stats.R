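test_that("rank-sum p-values are exact for small untied samples", {
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxonRankSum(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_equal(wilcoxonRankSum(c(1, 3, 9), c(1, 3, 9)), 1)
  # exact path agrees with full enumeration for all group sizes <= (5,5)
  set.seed(4)
  for (nx in 2:5) for (ny in 2:5) {
    x <- rnorm(nx); y <- rnorm(ny) + 0.5
    expect_equal(wilcoxonRankSum(x, y), oracleWilcoxonExact(x, y),
                 tolerance = 1e-12)
  }
})

test_that("point-biserial equals Pearson on 0/1 labels and the textbook formula", {
  expect_equal(pointBiserial(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(pointBiserial(c(2, 4, 2, 4), c(0, 0, 1, 1)), 0)
  expect_equal(pointBiserial(1:4, c(0, 0, 1, 1)), 0.8944272,
               tolerance = 1e-6)
  r0 <- pointBiserial(rep(3, 6), rep(c(0, 1), 3))
  expect_equal(as.numeric(r0), 0)
  expect_true(isTRUE(attr(r0, "degenerate")))
  set.seed(8)
  for (i in 1:10) {
    v <- rnorm(20); l <- rep(c(0, 1), each = 10)
    expect_equal(pointBiserial(v, l), oraclePointBiserial(v, l),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the hand step-up and its invariants", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  set.seed(15)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    m <- length(p) + sample(0:30, 1)
    adj <- bhFdr(p, m)
    expect_equal(adj, oracleBH(p, m), tolerance = 1e-12)
    # monotone in the sorted order; idempotent; bounded
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj <= 1 & adj >= p - 1e-12))
    expect_equal(bhFdr(adj), bhFdr(bhFdr(adj)), tolerance = 1e-12)
  }
  expect_error(bhFdr(c(0.5, 1.2)), "in \\[0, 1\\]")
})

test_that("group screening reports 63 alphabetical rows with the report schema", {
  set.seed(33)
  mkProf <- function(id, grp, shift) {
    v <- setNames(rnorm(63), featureNames63())
    v["nucleus_area"] <- v["nucleus_area"] + shift
    patientMean(list(v), id, grp)
  }
  profs <- c(lapply(1:8, function(i) mkProf(sprintf("l%02d", i), "low", 0)),
             lapply(1:8, function(i) mkProf(sprintf("h%02d", i), "high", 4)))
  rep_ <- compareGroups(buildCohort(profs))
  tab <- as.data.frame(rep_)
  expect_equal(nrow(tab), 63L)
  expect_identical(tab$feature, sort(featureNames63()))
  expect_identical(colnames(tab), c("feature", "p_raw", "p_adj", "r_pb",
                                    "mean_low", "se_low", "mean_high",
                                    "se_high"))
  expect_true(all(tab$p_adj >= tab$p_raw - 1e-12))
  # the planted feature dominates the screen
  expect_true("nucleus_area" %in% significantAdjusted(rep_))
  expect_gt(tab$r_pb[tab$feature == "nucleus_area"], 0)
  # per-group SE = sample sd / sqrt(n)
  area <- vapply(profs[1:8], function(p) p@means[["nucleus_area"]],
                 numeric(1))
  expect_equal(tab$se_low[tab$feature == "nucleus_area"],
               sd(area) / sqrt(8), tolerance = 1e-12)
})

test_that("constant features are reported but never significant", {
  set.seed(44)
  mkProf <- function(id, grp) {
    v <- setNames(rnorm(63), featureNames63())
    v["nucleus_extent"] <- 0.75
    patientMean(list(v), id, grp)
  }
  profs <- c(lapply(1:5, function(i) mkProf(sprintf("l%d", i), "low")),
             lapply(1:5, function(i) mkProf(sprintf("h%d", i), "high")))
  rep_ <- compareGroups(buildCohort(profs))
  tab <- as.data.frame(rep_)
  expect_equal(tab$p_raw[tab$feature == "nucleus_extent"], 1)
  expect_false("nucleus_extent" %in% significantRaw(rep_))
})
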