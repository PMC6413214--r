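Package: pigparts
Title: Bottom-Up Instance Detection of Group-Housed Pigs from Part Heatmaps and Association Vector Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the location and orientation of multiple pigs in top-down
    pen images by encoding four body parts (left ear, right ear, shoulder,
    tail) as unit-peak Gaussian heatmaps plus twelve pairwise association
    vector channels, decoding any such 16-channel map back into discrete
    oriented instances via regional peak detection, sub-pixel refinement and
    Hungarian bipartite grouping on association distances, and evaluating
    detections with a mutual nearest-neighbour (cross-check) matching metric.
    Includes a synthetic top-down scene generator, joint image/target
    augmentation, and a desk-scale trainable hourglass encoder-decoder
    network with max-unpooling indices, skip concatenations and a selective
    masked loss, together with effective-stride and receptive-field
    analytics for the architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    pracma,
    purrr,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
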