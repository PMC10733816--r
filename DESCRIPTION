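Package: deidr
Title: Hybrid De-Identification of Clinical Free Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-augmented pipeline for detecting and replacing sensitive
    health information (SHI) in unstructured clinical notes such as pathology
    reports. Reads and writes i2b2-style stand-off XML, repairs incorrectly
    cascaded tokens (missing spaces, comma-joined identifiers), encodes entity
    spans as BIO/BIESO token label sequences, trains a seeded window-feature
    sequence tagger with constrained Viterbi decoding, augments model output
    with regular-expression detectors for dates, phone numbers and URLs,
    generates realistic surrogates (shifted dates, keyed name and identifier
    replacement), and scores predictions with strict and relaxed micro-averaged
    precision, recall and F1. Includes a synthetic pathology-report corpus
    generator with gold annotations and controllable cascaded-token noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    IRanges,
    jsonlite,
    optparse,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
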