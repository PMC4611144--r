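Package: longvbm
Title: Longitudinal Functional PCA and Mixed-Model Morphometry for Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes longitudinal stacks of spatially normalized scalar
    images (e.g. RAVENS-type tissue-density maps) into subject-specific
    baseline, subject-specific longitudinal, and visit-specific components
    using high-dimensional longitudinal functional principal component
    analysis (HD-LFPCA) with method-of-moments covariance estimation in an
    SVD-reduced space and least-squares (BLUP-type) score prediction.
    Also provides the classical mass-univariate longitudinal voxel-based
    morphometry baseline (per-voxel linear mixed model with random intercept
    and slope, Benjamini-Yekutieli FDR control and cluster-extent
    thresholding), a geometric 2D phantom simulator with registration-error
    shifts and full ground truth, score-covariate association summaries, and
    a small reproducible pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    sandwich,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    lme4,
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
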