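Package: phaseviab
Title: Label-Free Live/Dead Cell Classification from Quantitative Phase Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A label-free viability assay pipeline for adherent cell cultures
    imaged by spatial light interference microscopy (SLIM). Reconstructs
    quantitative phase maps from four phase-shifted interferograms, derives
    three-class live/dead/background semantic ground truth from paired
    NucBlue/NucGreen fluorescence channels, trains an encoder-decoder
    semantic segmenter with a combined focal and dice loss, scores
    predictions with an object-based confusion/precision/recall/F1 metric,
    and tracks per-nucleus area and dry mass over time-lapse sequences.
    Ships a seeded synthetic time-lapse simulator that emulates the
    acquisition geometry (interferograms, phase, dual fluorescence,
    per-nucleus viability truth) so every stage is testable end to end on a
    laptop-scale CPU.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
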