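Package: srmap
Title: Successor-Representation Predictive Maps in Simulated fMRI Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-based analysis of anticipatory BOLD responses to learned
    visual sequences. Implements the successor-representation (SR),
    co-occurrence (CO) and null (H0) models of partial-sequence responses,
    their per-subject fitting and RMSE/BIC comparison, an exponential
    gamma-decay fit, constrained sequence and session design generation,
    GLM beta estimation with retinotopic voxel selection and control
    subtraction, hippocampal multivoxel location decoding with
    successor/predecessor evidence contrasts and time-resolved peak
    estimation, and a temporal-versus-spatial coactivation (tuning) model
    comparison. A seeded synthetic fMRI cohort generator with known ground
    truth makes the whole pipeline testable end to end by parameter and
    model recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
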