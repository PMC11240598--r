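Package: cytocluster
Title: Cell-Cluster Morphometry and Fractal Analysis for Liquid-Based
    Endometrial Cytology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of cell-cluster architecture in
    low-magnification liquid-based endometrial cytology fields.
    Converts field images to binary masks, measures per-cluster shape
    descriptors (area, perimeter, circularity, fitted-ellipse axes and
    angle, solidity, Feret diameters) and the box-counting fractal
    dimension of each field, and aggregates them to specimen level.
    Downstream statistics cover age- and cytology-adjusted logistic
    association with endometrial cancer and atypical hyperplasia, ROC
    analysis with DeLong confidence intervals and paired AUC comparison,
    binormal ROC sample-size computation, outcome-based survival
    cutpoint selection with a permutation min-p correction, Kaplan-Meier
    / log-rank summaries and Cox proportional-hazards models. A seeded
    synthetic cohort generator produces field images and clinical
    metadata with known class-conditional morphology for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    survival,
    S4Vectors,
    SummarizedExperiment,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    EBImage,
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
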