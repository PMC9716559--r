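Package: registercheck
Title: Detection of Sequence-Register Errors in Protein Models Using
    Predicted Inter-Residue Distances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Validates protein coordinate models against deep-learning
    predictions of inter-residue distances ("distograms"). Computes
    per-residue covariance-based validation metrics (weighted RMSD between
    observed and predicted distances, contact-map confusion metrics, their
    smoothed and spatial Z-score variants), trains a calibrated linear
    support-vector machine to flag residues lying within modelling errors,
    and aligns observed against predicted contact maps to detect
    sequence-register errors and propose the shifted register as a fix.
    Includes false-positive filters (predicted-contact density, pLDDT,
    superposition Q-score) and a synthetic-data module that generates toy
    folds, distograms and register-shift corruptions for testing and
    training.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    e1071,
    jsonlite,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
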