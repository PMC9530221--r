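Package: ctrlstates
Title: Brain-State Dynamics and Network Control Energy of Parcellated fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts recurrent brain states from parcellated BOLD time
    series by correlation-distance k-means with adjusted-mutual-information
    partition selection, characterizes their temporal dynamics (fractional
    occupancy, dwell time, appearance rate, transition probabilities),
    computes minimum control energies for transitions between states on a
    normalized structural connectome under uniform and receptor-weighted
    control inputs, evaluates the spatial specificity of receptor maps with
    spin-permutation null models, and relates energy-landscape flattening to
    the Lempel-Ziv entropy of binarized meta-state sequences.  Ships a
    synthetic-data generator emulating two-condition pharmacological fMRI
    cohorts for validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Matrix,
    pracma,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
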