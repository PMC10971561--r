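Package: needlegrade
Title: Damage-Level Grading of Conifer Canopies from UAV RGB Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A reproducible pipeline for grading insect defoliation damage of
    larch canopies from UAV RGB (and optionally multispectral) imagery.
    Computes per-canopy vegetation indices and grey-level co-occurrence
    matrix (GLCM) texture statistics, screens features by one-way ANOVA,
    extracts a low-redundancy sensitive subset with the successive
    projections algorithm (SPA), and classifies four leaf-loss damage levels
    with random forests and a small one-dimensional convolutional network.
    Includes a synthetic-scene generator that emulates damage-dependent
    canopy colour and texture so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
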