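Package: elrdd
Title: Ensemble Logistic Regression for Detecting Depression from Speech Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Speaker-independent classification of depression from per-recording
    acoustic speech features. Implements the ensemble logistic regression model
    (ELRDD): the 1992-feature MFCC/prosodic/spectral/glottal schema, the 15
    category-combination feature subspaces, per-subspace standardization and
    locally linear embedding with a deterministic out-of-sample extension,
    penalized maximum-likelihood logistic base classifiers, probability-sum
    ensemble scoring of recordings, and subject-level decision fusion over a
    subject's recordings (ELRDD-E). Includes stratified speaker-independent
    ten-fold cross-validation with sensitivity/specificity/accuracy reporting,
    one-way ANOVA with Fisher LSD post-hoc comparison of fold results, and a
    synthetic hierarchical dataset generator (subject random effects, gender
    strata, block-structured class signal) emulating the clinical speech
    database the method was designed for.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
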