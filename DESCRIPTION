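Package: hotex
Title: Higher-Order Cooccurrence Texture Analysis for Tissue Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Texture analysis of greyscale regions of interest built on
    higher-order grey-level cooccurrence matrices (orders 2, 3 and 5) and
    edge-orientation cooccurrence matrices (orders 2 and 3), with extended
    Haralick features, Laws microstructure statistics and Haar-wavelet
    subband entropies.  Includes correlation-based feature selection with
    genetic search, information-gain attribute ranking with MDL
    discretization, construction of a per-class textural model, and
    stratified cross-validated evaluation with support vector machine,
    multilayer perceptron and AdaBoost classifiers.  A seeded synthetic
    texture generator supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
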