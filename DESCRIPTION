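Package: openfield
Title: Deep Behavioral Phenotyping of Open-Field Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for unsupervised behavioral phenotyping of mice in the
    open field from pose-estimation keypoint time series. Builds
    rotation-invariant postural representations from pairwise marker distances
    with streaming PCA, expands them into Morlet wavelet spectrograms over
    dyadically spaced frequencies, clusters posture dynamics into a fine
    behavioral vocabulary with k-means and nearest-neighbor reembedding, and
    derives ethogram usage and habituation metrics, spatial occupancy,
    grooming-mode decomposition, quadruped gait stride and limb-phase
    analysis with walk/trot classification, and compositional statistics of
    behavioral time budgets (isometric log-ratio coordinates, rank-based
    multivariate permutation tests, bootstrap log-ratio differences).
    Includes a synthetic open-field trial generator with known behavioral and
    gait ground truth, plus centroid tracking and egocentric alignment for
    raw grayscale video stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
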