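Package: famclone
Title: Family-Aware Mixed Models for Early-Stage Clonal Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for early-generation clonal selection in autotetraploid
    potato breeding programs where test clones descend from full-sib families.
    Provides a residual maximum likelihood (REML) engine with Henderson's
    mixed-model equations for single-trial and multi-environment-trial
    analyses with and without a nested family effect, heterogeneous block and
    residual variances, and unstructured across-season genetic covariances;
    best linear unbiased prediction (BLUP) of family, clone-within-family and
    total genotypic effects with prediction error variances and selection
    accuracies; model comparison by AIC and likelihood-ratio tests with
    chi-square and normal confidence intervals; selection-strategy comparison
    by Czekanowski coincidence, Spearman rank correlation and a
    factor-analytic (FAI-BLUP) ideotype-distance index; and a synthetic trial
    generator for augmented block and partially replicated field designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
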