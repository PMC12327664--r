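Package: benthoscan
Title: Grid-Point and Patch-Based Automated Annotation of Benthic Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-house automated image analysis for benthic habitat survey
    imagery. Implements a sparse grid-point annotation model (a modified
    residual backbone with reduced late-stage downsampling, per-stage
    coordinate rescaling, multi-block feature sampling and a spatial
    self-attention module) and an image-level presence/absence model over
    three overlapping large patches, together with CATAMI-broad label
    consolidation, train/test splitting by image, confusion-matrix and
    precision/recall evaluation, and a procedural synthetic-scene generator
    that provides ground-truth imagery for testing both models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
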