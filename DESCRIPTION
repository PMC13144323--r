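Package: chromacyte
Title: Chromatin-State Morphometry and Patient Prediction from Nuclear
    Imaging of Immune Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for chromatin-imaging
    cytometry of peripheral blood mononuclear cells: seeded synthetic 3D
    imaging cohorts with planted disease-specific subpopulation structure,
    conditional multi-Otsu nuclear segmentation with 6-connectivity labeling
    and physical diameter filters, handcrafted nuclear and dense-chromatin
    morphometrics (including radial domain placement and boundary
    separation), a convolutional variational autoencoder for latent
    chromatin descriptors, four-step per-condition class balancing,
    consensus Leiden clustering with co-association matrices and adjusted
    Rand index stability scoring, cluster-enrichment profiles with
    leave-one-patient-out random-forest prediction and permutation nulls,
    kNN label transfer with confidence-based rejection, and
    immunofluorescence and compression-assay quantification statistics
    (Otsu positivity, triangle-threshold viability, Hotelling T-squared).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    pROC,
    randomForest,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
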