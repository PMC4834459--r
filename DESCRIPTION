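Package: ppiMLDA
Title: Psychophysiological Interaction Maps and Maximum-Uncertainty LDA
    for fMRI Group Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying subjects from voxelwise
    psychophysiological interaction (PPI) contrast maps. Provides a
    seeded synthetic-data generator for group-labeled PPI-like maps and
    event-related BOLD time series, voxelwise GLM t-map estimation with
    PPI design assembly, a maximum-uncertainty (maximum-entropy)
    regularized linear discriminant classifier with discriminative-voxel
    feature selection, a leave-one-subject-out cross-validation driver,
    and evaluation statistics (confusion metrics, ROC/AUC, exact binomial
    test against chance, decision-value correlations, rank-sum
    comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
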