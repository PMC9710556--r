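Package: orgeval
Title: Evaluation of Multi-Channel Predictions of Subcellular Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metrics and statistical tests for judging how well multi-channel
    fluorescence predictions (in silico labeling) reproduce the organization of
    real cells. Provides pixel-level organelle exclusivity metrics and the
    matching loss term for model retraining; object-level shape comparison via
    spherical-harmonic surface descriptors, PCA embedding and a k-nearest-
    neighbour purity divergence with permutation testing; spatial-distribution
    comparison in a normalized unit-sphere cell frame with Gaussian kernel
    density estimation and Kullback-Leibler divergence; simple instance
    segmentation and Jaccard similarity; and a synthetic 3D cell image
    generator with ground-truth bookkeeping used as a controlled test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
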