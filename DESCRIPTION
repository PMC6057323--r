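Package: nucmorph
Title: Nuclear Morphometry and Texture Screening for H&E Histopathology
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end nuclear morphometry for light-microscopy images of
    H&E-stained cervical biopsy tissue. Segments nuclei (Gaussian smoothing,
    Canny edge detection, morphological closing and hole filling, size
    filtering), quantifies 63 texture and morphology features per nucleus
    (histogram moments, Haralick co-occurrence, gray-level run-length,
    Daubechies-2 wavelet detail statistics, Tamura coarseness/contrast/
    roughness, local binary patterns, and regionprops-style shape
    descriptors), aggregates nuclei to per-patient mean feature vectors,
    and screens features between low-grade and high-grade CIN groups with
    the Wilcoxon rank-sum test, point-biserial correlation, and
    Benjamini-Hochberg FDR correction. Includes a seeded synthetic-cohort
    generator with ground-truth masks and planted group effects so every
    pipeline stage is testable without clinical material.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    tiff,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
biocViews: CellBiology, FeatureExtraction, Classification, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
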