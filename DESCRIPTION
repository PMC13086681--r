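Package: ecapri
Title: Imaging Biomarkers and Cox Risk Scoring for Post-TAVI Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for one-year mortality risk scoring after transcatheter
    aortic valve implantation (TAVI) from pre-operative CT. Implements
    thoracic aortic calcium (TAC) segmentation scaffolding (location masks,
    masked binary cross-entropy, HU windowing, patch sampling, an
    adaptive-threshold baseline segmenter), extraction of CT imaging
    biomarkers (chamber volumes, vessel radii, emphysema ratio, L3 muscle
    area, body-surface-area indexing), the mean-centered Cox linear CAPRI
    and eCAPRI scores with published coefficients packaged as defaults, the
    three-step biomarker selection pipeline (univariate Cox screen,
    correlation pruning with Spearman/tetrachoric/polychoric dispatch,
    exhaustive cross-validated subset search), and score evaluation
    (AUC with bootstrap confidence intervals, paired permutation
    comparison, calibration, Brier skill score). Ships CT phantom and
    survival-cohort simulators so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
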