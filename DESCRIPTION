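Package: dabquant
Title: Whole-Slide DAB Immunohistochemistry Positive-Area Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tile-based quantification of DAB-stained macrophages in
    whole-slide brightfield immunohistochemistry scans. Implements an RGB
    channel transform to a chromogen signal, Gaussian smoothing, binarization
    at a base threshold with a robustness window, connected-component
    labeling, area-based filtering and clustering of feature regions,
    normalization of segmented area to tissue-section area per donor, and
    one-way ANOVA with Bonferroni post-hoc comparison of donor groups.
    Includes a synthetic H-DAB tile and cohort generator with known ground
    truth so the whole pipeline is testable without slide scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
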