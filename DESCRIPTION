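Package: conformotif
Title: Interpretable Conformational-State Classification of Receptor
    Trajectories with Layer-Wise Relevance Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Labels molecular-dynamics frames of a G-protein-coupled receptor
    as active, intermediate or inactive from a probe-pair alpha-carbon
    distance, classifies frames with a block-structured one-dimensional
    convolutional neural network trained on per-residue center-of-mass
    coordinates, and attributes predictions to individual residues and
    receptor regions via layer-wise relevance propagation (the basic LRP-0
    rule and the epsilon-stabilised LRP-epsilon rule). Downstream analysis
    aggregates relevance to residues and regions, extracts key-residue motif
    tables via interquartile-range fences, and summarises region-level
    contributions. A synthetic trajectory generator with planted
    state-discriminative residues makes the whole pipeline testable without
    external simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
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
    caret,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
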