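Package: parcelgrowth
Title: Cross-Classified Growth-Curve Modelling of Parcellated Task-fMRI Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal growth-curve analysis of parcel-level
    task-fMRI contrast estimates in accelerated cohort designs. Extracts and
    harmonizes parcel means from NIfTI contrast images against an integer-labeled
    atlas (within-parcel standardization, grand-mean outlier exclusion), and fits
    cross-classified (participant by parcel) polynomial mixed-effects growth
    models with categorical moderators using a from-scratch profiled ML/REML
    deviance over sparse penalized normal equations. Provides AIC model
    comparison, Wald coefficient and contrast inference with Satterthwaite
    degrees of freedom, simple slopes of polynomial age trajectories, Bonferroni
    correction, trajectory prediction, and a synthetic-cohort generator for
    simulation-based parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    lme4,
    lmerTest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
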