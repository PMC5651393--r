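Package: dfncpipe
Title: Preprocessing Order Effects on Dynamic Functional Network Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the ordering of fMRI preprocessing steps
    (spike regression, motion regression, smoothing, group ICA, interpolation,
    band-pass filtering) affects dynamic functional network connectivity (dFNC)
    analyses and patient-versus-control classification. Includes a seeded
    synthetic 4D cohort generator with planted spatial sources and connectivity
    states, DVARS spike detection, nuisance regression, desk-scale group spatial
    ICA with multi-run stability indices, sliding-window correlation with
    L1-norm k-means brain states, occupancy-rate statistics, MANOVA/ANOVA
    pipeline comparisons, and covariate-adjusted least-squares SVM
    classification with nested leave-one-out cross-validated model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
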