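Package: phenoscreen
Title: Local High-Content-Microscopy Phenotype Scoring Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cloud-free toolkit for scoring protein-localization phenotypes in
    high-content fluorescence microscopy screens. Provides focus-based image
    quality control (variance-of-Laplacian with air-bubble and overexposure
    suppression), bounding-box cell detection with a 14-transform training
    augmentation scheme and precision/recall/average-precision evaluation,
    unsupervised phenotype discovery (convolutional feature extraction,
    PCA + UMAP reduction, noise-cluster removal, silhouette-guided spectral
    subclustering, centroid exemplars), and supervised phenotype scoring
    (per-variant localization distributions and correlation of the nuclear
    fraction with orthogonal loss-of-function scores). A synthetic
    fluorescence-field generator with full ground truth makes every stage
    testable end to end without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    FNN,
    graphics,
    jsonlite,
    nnet,
    stats,
    tiff,
    tools,
    utils,
    uwot,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
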