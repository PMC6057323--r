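---
title: "Nuclear morphometry and two-group screening for H&E histopathology"
author: "nucmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry and two-group screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmorph)
```

## The problem

Grading cervical intraepithelial neoplasia (CIN) on H&E-stained biopsy
material relies on the pathologist's visual assessment of nuclear atypia:
abnormal nuclear size, shape and chromatin texture. That assessment is
subjective, and inter-observer agreement on the low-grade/high-grade
boundary is known to be modest. `nucmorph` implements a fully computational
counterpart: segment nuclei from light-microscopy images, quantify each
nucleus with 63 texture and morphology features, average them to one
63-feature vector per patient, and screen every feature for a difference
between the low-grade and high-grade patient groups with nonparametric
statistics and multiple-testing control.

The package is organised around that four-stage pipeline:

1. **Segmentation** (`segmentNuclei()`): grayscale conversion (BT.601
   luminance), Gaussian smoothing, Canny edge detection, morphological
   closing and hole filling, a 500-pixel minimum-area filter, and a logical
   AND with the grayscale image, yielding one masked crop per nucleus.
2. **Features** (`nucleusFeatures()`): 54 texture features (histogram
   moments; 13 co-occurrence features; 5 run-length features; 24 statistics
   of second-level Daubechies-2 wavelet detail coefficients; 6 Tamura
   features; 2 local-binary-pattern features) plus 9 regionprops-style
   morphology features.
3. **Aggregation** (`patientMean()`, `buildCohort()`): nucleus-level
   pooling across all of a patient's images into a per-patient mean vector,
   assembled into a `NuclearCohort` (a `SummarizedExperiment`).
4. **Screening** (`compareGroups()`): per-feature two-sided Wilcoxon
   rank-sum test, Benjamini–Hochberg FDR adjustment over m = 63 tests,
   point-biserial correlation with the group label (low = 0, high = 1),
   and per-group mean ± standard error.

Because clinical slides cannot ship with a package, a seeded synthetic
generator (`simulateCohort()`, `generateCohort()`) provides H&E-like
fields with known ground truth, and every stage is validated against it.

## Segmentation: model and parameter choices

The chain treats nuclei as dark, roughly elliptical objects on a lighter
background — exactly what hematoxylin staining produces at 400×. The
smoothing stage is a Gaussian blur (`smoothingSigma = 2` px by default).
A true Laplacian-of-Gaussian response is available behind
`smoothingMode = "log"`, but the default is plain Gaussian smoothing: the
Canny detector that follows needs a smoothed *intensity* image, and a
band-pass input would double-differentiate the data.

Canny hysteresis thresholds default to automatic selection: the high
threshold by Otsu's criterion on the gradient-magnitude distribution, and
the low threshold at 0.4 × high, a conventional ratio. The closing element
is a disk of radius 3 px — large enough to bridge 2-px contour gaps,
small enough not to merge neighbouring nuclei. The minimum component area
is 500 px, appropriate for nuclei tens of pixels across; components
touching the frame border are discarded because their morphology would be
truncated. Connectivity is 8-connected throughout, and touching nuclei are
*not* split (no watershed): clumps that survive the chain are treated as
single regions, a stated non-goal.

## Feature conventions

Several conventions are deliberate and fixed:

* **Masked domain.** Histogram, co-occurrence, run-length, LBP and Tamura
  statistics use in-mask pixels only (pairs and runs require all
  participating pixels in-mask; runs break at the mask boundary). The
  wavelet transform needs a rectangular grid, so it operates on the
  bounding-box crop with zero background — the "final image" the
  segmentation chain produces. Excluding background from point statistics
  prevents the zeros from dominating the moments.
* **Quantization.** Co-occurrence and run-length levels use 16 equal-width
  bins over the fixed range [0, 255], not per-nucleus min–max, so contrast
  information stays comparable across nuclei.
* **Direction pooling.** The four directional co-occurrence matrices
  (0°, 45°, 90°, 135°, distance 1) are counted symmetrically, summed and
  normalized into one matrix giving 13 features; the five run-length
  ratios are computed per direction and averaged. This matches the
  published feature counts (13 + 5).
* **Logarithms** are natural, with 0·log 0 ≡ 0; correlation is defined 0
  when a marginal standard deviation vanishes.
* **Standard deviations.** Histogram and LBP moments are population (1/N)
  moments, as their defining formulas print; the wavelet
  standard-deviation statistic uses the sample (n−1) denominator, the
  convention of the `std`-family functions it names. The inconsistency is
  faithful to the two printed sources.
* **Tamura.** Scales k = 0..5; neighborhood averages over 2^k × 2^k
  windows (border-clamped), directional differences at offset
  max(1, 2^(k−1)) — the k = 0 offset of half a pixel is not realizable on
  the grid. Ties across k are broken to the smallest k, so a constant
  region has coarseness 1. Coarseness 2–4 are the 3-bin equal-width
  histogram of S_best over [1, 32] in percent; contrast uses the original
  exponent 1/4 on kurtosis.
* **LBP** codes read the exponent as 2^p with p the summation index
  (a constant exponent would collapse all codes); neighbors are sampled
  bilinearly at radius 1 and the code distribution's mean and population
  sd are reported. A 1e-7 tolerance in the sign function absorbs bilinear
  round-off when neighbor and center are equal, so constant regions code
  to 255 exactly.
* **Morphology.** Perimeter is the 8-connected outer boundary chain length
  with √2 diagonal steps; convex area counts pixel centers inside the
  convex hull of foreground pixel centers (so digitally convex shapes
  reach solidity 1); moment-ellipse axes include the +1/12 per-pixel
  variance correction. Note that with the standard definition
  solidity = area / convex area *decreases* as borders grow irregular;
  the screening stage treats each feature's direction as an empirical
  outcome, not an assertion.
* **Missing values.** Degenerate statistics (e.g. skewness of a constant
  nucleus, wavelet features of a crop smaller than 8×8) are carried as
  `NA`, skipped by the per-patient mean, and excluded pairwise from the
  per-feature comparison. They are never silently zeroed.

## Statistics

The two patient groups are independent, so "Wilcoxon" is read as the
rank-sum (Mann–Whitney) test: exact enumeration when the combined sample
is ≤ 25 without ties, otherwise the normal approximation with mid-rank tie
correction and continuity correction. The point-biserial correlation is
computed as the Pearson correlation against the 0/1 label, which equals
the textbook mean-difference formula. FDR control is the
Benjamini–Hochberg step-up over m = 63 tests (configurable); applying it
at rank 1 to the smallest p-value of the bundled reference screening table
(`cinScreenReference()`) reproduces that table's printed adjusted value,
which anchors the m = 63 convention. Full precision is carried throughout;
p-values printed at 3 significant figures can tie in print yet adjust
differently, which is expected behaviour.

## What the synthetic generator emulates — and what it does not

`groupParams("low_like")` / `groupParams("high_like")` encode the
group-difference directions the screening stage is expected to recover:
larger nuclei (base radius mean 20 vs 16 px), more irregular boundaries
(radial harmonic amplitude 0.15 vs 0.05), coarser interior texture
(Gaussian-field correlation length 6 vs 3 px) and stronger intensity
inhomogeneity (sd 16 vs 10), on a shared bright background (200 ± 6) with
dark nuclei (mean 100). Nuclei are star-convex shapes — an ellipse
modulated by radial harmonics 3–6 with a single amplitude knob — placed by
dart throwing with ≥ 4 px gaps; interiors are Gaussian random fields whose
correlation length maps monotonically to measured Tamura coarseness. The
default cohort is 22 patients per group with 4 or 5 images each
(alternating), at a 512 × 512 frame.

At 400× the study's nuclei span roughly 36–44 px in equivalent diameter;
the generator's 32–40 px at a 512 × 512 frame keeps that geometry while a
whole cohort (≈ 200 images) processes in a few minutes. The generator does
*not* emulate overlapping or clumped nuclei, epithelial architecture,
chromatin substructure, staining variation or H&E colour — so passing
recovery tests demonstrate that the pipeline measures what was planted
under clean conditions, not that it matches expert segmentation of real
slides (which the original evaluation could only quantify with an expert
in the loop).

The generator's minimum base radius is 14 px, so every planted nucleus
exceeds the 500-px size threshold by construction and recovery tests are
exact counts. Sub-seeds are derived arithmetically per patient and image,
so any sub-unit can be regenerated independently and identical spec + seed
is bit-identical.

## Calibration design

The type-I calibration (`typeICalibration()`) generates null cohorts in
which both groups share the `low_like` preset and records the fraction of
the 63 raw p-values below 0.05. Two design choices matter:

* **Group size 8 + 8.** The exact rank-sum test is discrete: at nominal
  0.05 its achievable size is 0.041 at (6,6) and 0.043 at (10,10), but
  0.0499 at (8,8) — computed by full enumeration of the null distribution
  before any calibration was run. At 8 + 8 the null rejection rate is
  essentially nominal, so the calibration measures the pipeline, not test
  discreteness.
* **Reduced scale.** Each replicate uses one 160 × 160 image with 2 nuclei
  per patient. The calibration property concerns the screening statistics
  under the null; image scale only sets how noisy each patient's mean
  vector is, and the reduced frame makes hundreds of replicates
  affordable. Features within one replicate are correlated (they derive
  from the same patients), which inflates the variance of the observed
  fraction relative to an independent binomial — the replicate count keeps
  that within the quoted bounds.

## Numerical and degenerate-input choices

* 16-bit inputs are rescaled to 8 bits by integer division by 257 (fixed
  rescale, not per-image normalization).
* Canny on a constant image returns an empty mask (a 1e-6 guard absorbs
  FFT round-off in the gradient).
* Empty masks, multi-component masks, and regions without a valid pixel
  pair raise informative errors at the family level and become `NA`s at
  the vector level; the batch never aborts.
* All randomness flows from explicit integer seeds; reruns are
  byte-identical, which the suite asserts on written CSVs.

## Worked example

```{r example, eval = FALSE}
library(nucmorph)

# a small two-group synthetic cohort
spec <- cohortSpec(nPatientsPerGroup = 4L, seed = 11L,
                   imageSize = c(256L, 256L))
report <- runPipeline(spec = spec, outDir = "run1")
report
as.data.frame(report)[1:5, ]
significantAdjusted(report)
```

## Known limitations

* No separation of touching nuclei; clumps bias morphology upward.
* The segmentation defaults were chosen for high-contrast H&E-like
  material; faint staining will need the exposed thresholds.
* Solidity's direction under boundary irregularity follows the standard
  definition (decreasing), which published tables do not always share.
* The reference screening table carries printed (3-significant-figure)
  precision; arithmetic anchors computed from it inherit that rounding.
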