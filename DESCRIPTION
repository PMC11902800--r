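Package: leafmsi
Title: Spatial-Spectral Analysis of Backlit Multispectral Corn Leaf Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Processing and analysis pipeline for snapshot multispectral
    transmittance images of single corn leaves, aimed at nitrogen-treatment
    classification. Covers flat-field calibration against per-band white
    references, Gabor-filter detection and harmonic inpainting of thin
    guard-thread occlusions, NDVI-based leaf segmentation, pairwise
    normalized-difference index heatmaps, principal-axis leaf zoning, vein
    segmentation, statistical and gray-level co-occurrence texture features,
    and cross-validated random-forest treatment classification. Includes a
    synthetic backlit leaf-scene generator with ground-truth masks so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Matrix,
    randomForest,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
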