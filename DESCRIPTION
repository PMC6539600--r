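Package: tremorsdh
Title: Sum-and-Difference-of-Histograms Texture Features for Hand-Tremor
    Severity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adapts the sum-and-difference-of-histograms (SDH) texture
    technique from 2D images to 1D hand-motion signals captured with a
    leap-motion controller, and classifies postural/kinetic tremor into
    MDS-UPDRS severity levels 0-2. Provides capture-file and cohort-manifest
    I/O in a fixed 40-channel schema, a synthetic tremor-cohort simulator,
    windowed SDH feature extraction (nine texture features including the
    contrast and homogeneity headliners), a repeated 70/30 evaluation
    harness with bagged decision trees and nearest-neighbour classifiers,
    and drivers for coordinate-selection, per-feature and window-size
    sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
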