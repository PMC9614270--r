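Package: podeeg
Title: Postoperative Delirium Risk Prediction from Intraoperative Frontal EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for predicting the risk of postoperative
    delirium (POD) in older surgical patients from 4-channel frontal EEG
    (Fp1, Fp2, F7, F8) recorded by depth-of-anesthesia monitors, combined
    with clinical covariates available in the operating room. Implements
    amplitude/frequency artifact cleaning and segmentation, burst-suppression
    quantification (burst suppression ratio and longest suppression phase),
    Welch spectral frames, multi-band covariance features on the manifold of
    symmetric positive definite matrices with OAS shrinkage, Riemannian
    potato outlier rejection and tangent-space projection, two-level
    undersampled bagging with weighted SVM base learners, balanced random
    forests on clinical features, g-mean threshold shifting with a max/min
    probability fusion rule, stratified cross-validation with
    medication-group routing, frozen-model transfer to new cohorts, and a
    synthetic cohort generator for fully reproducible benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io.R'
    'synthetic.R'
    'preprocess.R'
    'burst.R'
    'spectral.R'
    'spd.R'
    'riemann.R'
    'frame_ensemble.R'
    'patient_model.R'
    'fusion.R'
    'pipeline.R'
    'evaluation.R'
    'cli.R'
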