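Package: facemvpa
Title: Synthetic Block-Design fMRI Simulation and Multivoxel Decoding of Face Identity
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating block-design BOLD fMRI experiments with
    embedded face-selective regions carrying a ground-truth identity-coding
    multivoxel pattern, and for analysing them with the classical decoding
    chain: localizer general linear models, contiguous fixed-size region-of-
    interest construction, percent-signal-change extraction, session-wise
    preprocessing with leave-one-session-out linear support vector machine
    classification, overlapping-box search-light mapping, group inference
    with Bonferroni and Benjamini-Hochberg corrections, and stimulus
    pixel-correlation similarity checks. Every analysis stage is exercisable
    without any real fMRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
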