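# Per-feature two-group screening: Wilcoxon rank-sum, point-biserial
# correlation, Benjamini-Hochberg FDR, and the report table.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when the combined sample size is at most 25 and there
#' are no ties; otherwise the normal approximation with mid-rank tie
#' correction and continuity correction. Identical constant samples give
#' p = 1.
#'
#' @param x,y numeric samples for the two independent groups.
#' @return two-sided p-value.
#' @export
wilcoxonRankSum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L) return(1)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 25L) && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

#' Point-biserial correlation
#'
#' Pearson product-moment correlation between feature values and the 0/1
#' group label (low = 0, high = 1): positive values mean the feature is
#' higher in the high-grade group. Zero-variance features yield `r = 0`
#' with attribute `degenerate = TRUE`.
#'
#' @param values numeric feature values.
#' @param labels 0/1 group labels of the same length.
#' @return correlation in `[-1, 1]`.
#' @export
pointBiserial <- function(values, labels) {
  if (length(values) != length(labels))
    stop("'values' and 'labels' must have equal length")
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) != 2L)
    stop("'labels' must contain both 0 and 1")
  if (stats::var(values) == 0) {
    r <- 0
    attr(r, "degenerate") <- TRUE
    return(r)
  }
  stats::cor(values, labels)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with p-values sorted ascending,
#' `adj[(i)] = min over j >= i of (m * p[(j)] / j)`, capped at 1 and mapped
#' back to input order. `m` defaults to the number of p-values but can be
#' set larger (e.g. 63 when only a subset of a 63-feature screen is
#' supplied).
#'
#' @param p numeric p-values in `[0, 1]` (`NA` allowed, passed through).
#' @param m number of tests for the correction.
#' @return adjusted p-values in input order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(p, m = length(p)) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]")
  if (m < sum(ok)) stop("'m' must be >= the number of p-values")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH", n = m)
  out
}

#' Screen all 63 features between the low and high groups
#'
#' For each feature: two-sided Wilcoxon rank-sum p-value, BH-adjusted
#' p-value over `mTests` tests, point-biserial correlation with the group
#' label (low = 0, high = 1), and per-group mean and standard error
#' (sample sd / sqrt(n)). Patients with a missing value for a feature are
#' excluded from that feature's comparison only (pairwise deletion).
#' Features with fewer than 2 defined values in either group are reported
#' with missing statistics. Rows are ordered alphabetically by feature
#' name.
#'
#' @param cohort a [NuclearCohort] with both groups non-empty.
#' @param alpha significance level (default 0.05).
#' @param mTests number of tests for the FDR correction (default 63).
#' @return a [ScreeningReport].
#' @export
compareGroups <- function(cohort, alpha = 0.05, mTests = 63L) {
  feats <- cohortFeatures(cohort)
  grp <- cohortGroups(cohort)
  if (!all(c("low", "high") %in% grp))
    stop("both groups must be non-empty")
  rows <- lapply(rownames(feats), function(f) {
    v <- feats[f, ]
    lo <- v[grp == "low"]; hi <- v[grp == "high"]
    lo <- lo[!is.na(lo)]; hi <- hi[!is.na(hi)]
    if (length(lo) < 2L || length(hi) < 2L) {
      return(data.frame(feature = f, p_raw = NA_real_, p_adj = NA_real_,
                        r_pb = NA_real_, mean_low = NA_real_,
                        se_low = NA_real_, mean_high = NA_real_,
                        se_high = NA_real_))
    }
    p <- wilcoxonRankSum(lo, hi)
    r <- as.numeric(pointBiserial(c(lo, hi),
                                  rep(c(0, 1), c(length(lo), length(hi)))))
    data.frame(feature = f, p_raw = p, p_adj = NA_real_, r_pb = r,
               mean_low = mean(lo), se_low = sd(lo) / sqrt(length(lo)),
               mean_high = mean(hi), se_high = sd(hi) / sqrt(length(hi)))
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- bhFdr(tab$p_raw, m = max(mTests, sum(!is.na(tab$p_raw))))
  tab <- tab[order(tab$feature), , drop = FALSE]
  rownames(tab) <- NULL
  new("ScreeningReport", table = tab, alpha = alpha,
      mTests = as.integer(mTests))
}
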