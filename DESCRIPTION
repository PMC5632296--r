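Package: tipscan
Title: Sliding-Window CNN Localization of Plant Root and Shoot Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-based plant-phenotyping pipeline that finds point
    features (root tips, leaf and ear tips and bases) in seedling root-system
    and wheat-shoot photographs. Point-annotated images are turned into
    balanced patch-classification datasets with hard-negative mining, small
    convolutional networks are trained on the patches, whole images are
    scanned with a sliding window to yield per-class probability maps, maps
    are reduced to discrete tip coordinates by morphological erosion and
    connected components, and a root-trait vector (tip count, convex hull
    area, bounding-box extents, depth-strip counts, total length, centre of
    mass) is derived for downstream quantitative-genetics analysis. A
    synthetic scene generator with exact ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
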