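Package: ductscape
Title: Immune Microecology of Ductal Carcinoma In Situ from Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for mapping the immune microecology of
    ductal carcinoma in situ (DCIS) on histology tiles. Provides a seeded
    synthetic-histology generator with exact ground truth, tissue
    segmentation, an inception-block encoder-decoder for duct detection and
    segmentation with boundary-weighted multi-output loss, a dense-inception
    single-cell detector trained on distance-regularised proximity maps with
    Hausdorff-distance monitoring, a neighbouring-ensemble single-cell
    classifier, and the ecological core: invasive-compartment exclusion,
    Voronoi tessellation seeded on duct centroids, quadrat counting, and the
    Morisita-Horn DCIS immune colocalisation score, together with
    segmentation and detection evaluation metrics and group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
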