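Package: arcnet
Title: Angle-Relation Connection Networks and Geometric Graph Features for
    EEG Dementia Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transforms single-channel EEG segments into directed weighted
    graphs with the Angle-Relation Connection (ARC) rule, a geometry-aware
    time-series-to-network mapping in the visibility-graph family. Computes
    a 15-entry graph feature vector per segment, including the Weighted
    Angular Irregularity Index (WAII) and the Curvature-Based Edge Feature
    Index (CBEFI), selects discriminative feature subsets with an Ant Colony
    Optimization wrapper, and evaluates dementia-subtype classification
    (Alzheimer's disease, frontotemporal dementia, healthy controls) with
    five classifiers and standard confusion-matrix metrics. Includes a
    synthetic EEG cohort generator so the full pipeline is testable without
    external recordings, plus readers for CSV, EDF and EEGLAB SET files in
    a BIDS layout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    Matrix,
    ranger,
    e1071,
    rpart,
    class,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
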