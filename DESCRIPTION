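Package: tomatovision
Title: Vision-Based Tomato Quality Inspection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An image-analysis pipeline for tomato fruit quality inspection
    from chamber photographs. Implements rank-order noise filtering,
    two-frame background-difference segmentation, colour-fraction and
    local-entropy texture features, pattern-weighted binary area estimation,
    k-means colour clustering in CIELAB chromaticity, and Gaussian
    discriminant (LDA/QDA), PCA and k-nearest-neighbour classifiers that
    grade maturity, flag infected fruit and assign a disease archetype.
    Ships a deterministic synthetic tomato-image generator with ground-truth
    annotations so the full pipeline is testable without camera data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    tiff,
    jpeg,
    farver,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    class,
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
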