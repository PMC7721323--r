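Package: rosettephen
Title: Leaf-State-Aware Trait Extraction from Top-View Plant Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts morphometric and color-index traits from top-view
    images of single plant rosettes using multi-class semantic segmentation
    masks that distinguish green, anthocyanin-rich, and senescent leaf
    tissue. Provides three mask vocabularies (one-, two-, and three-class),
    mask coarsening between them, a classical CIELAB-threshold segmentation
    baseline with optional multi-scale score averaging, mean
    intersection-over-union evaluation against ground truth, a
    scatter-gather batch pipeline producing one tidy results table plus
    diagnostic images, and a synthetic rosette generator with exact
    ground-truth masks for testing every step without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    jpeg,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
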