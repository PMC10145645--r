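Package: gazestrat
Title: Gaze-Strategy Analysis for Matrix Reasoning Eye-Tracking Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for eye-tracking studies of matrix reasoning
    strategy. Reads fixation-event tables, tags fixations with areas of
    interest (nine matrix cells and eight answer choices), applies the
    standard fixation and participant quality filters, and computes fourteen
    participant-level gaze metrics (transition counts, dwell ratios, visit
    rates, latencies). Trial scanpaths are represented as AOI transition
    matrices and classified into two strategy clusters (constructive-matching
    versus hybrid scanning) with canonically oriented two-centroid k-means;
    clusters are contrasted with Jeffreys-Zellner-Siow Bayes factors. Gaze
    metrics predict cognitive scores through LASSO regression with the
    penalty chosen by leave-one-out cross-validated RMSE on a train split,
    and dependent correlations are compared with Steiger's z test and
    Fisher-z confidence intervals. A synthetic scanpath-and-score generator
    with planted strategy labels makes the whole pipeline runnable and
    testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    Rcpp,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
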