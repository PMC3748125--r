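Package: agglearn
Title: Learned Hierarchical Agglomeration of Superpixel Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical agglomerative segmentation of 2D and 3D label
    volumes from an initial superpixel oversegmentation, with a merge
    priority function learned by an active training loop that compares
    candidate merges against the best agglomeration derived from a gold
    standard.  Includes flat-graph learning and a Rand-index-guided
    (LASH-style) variant, region/boundary feature maps over pixel cue
    channels, a seeded synthetic phantom generator with watershed
    superpixels, and a segmentation evaluation suite: variation of
    information with split-VI curves and per-segment breakdown, Rand and
    adjusted Rand indices, segmentation covering, and ODS/OIS threshold
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    igraph,
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    rhdf5,
    png,
    withr,
    optparse
Config/testthat/edition: 3
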