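Package: mcseg
Title: Two-Stage Convolutional Detection and Segmentation of Mammographic
    Microcalcifications
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and segments breast microcalcifications in grayscale
    mammogram-like images with a two-stage patch-based convolutional pipeline:
    a detector network screens overlapped image tiles for candidate regions,
    and a segmentator network classifies every pixel inside flagged regions,
    producing a binary lesion mask that is then analysed for clusters by the
    radiological density rule (more than five distinct microcalcifications per
    square centimetre). Includes a synthetic phantom generator with pixel-exact
    ground truth, a four-class patch taxonomy with a SQLite-backed patch index
    and balanced augmented minibatch sampling, a compact CNN engine
    (3x3 convolutions, batch normalization, dropout, Adam) written with
    RcppArmadillo, and an evaluation suite (per-class patch error rates,
    whole-image pixel accuracy and false-positive rate, lesionwise recall).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    DBI,
    RSQLite,
    rhdf5,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    withr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    png,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    knitr
Config/testthat/edition: 3
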