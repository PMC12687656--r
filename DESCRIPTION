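Package: slipsynergy
Title: Muscle Synergy Analysis of Reactive Balance Responses to Stance-Slip
    Perturbation Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing neuromuscular adaptation
    during treadmill slip-perturbation balance training. Processes
    multi-channel surface EMG into binned activation envelopes, extracts
    muscle synergies by non-negative matrix factorization with
    variance-accounted-for dimensionality selection, pools and clusters
    synergies across participants with silhouette-guided k-means, matches
    synergy modes across training stages by Pearson correlation, computes
    temporal activation features and reactive-step kinematics (step timing
    and geometry, centre-of-mass state, trunk and arm angles, fall
    classification), and runs the paired statistical comparisons between
    early and late training stages. Includes a seeded synthetic-session
    generator with known ground truth for validating every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    graphics,
    jsonlite,
    nortest,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
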