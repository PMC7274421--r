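Package: metaGP
Title: Genomic and Metabolic Prediction in Nested Association Mapping
    Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Whole-genome and whole-metabolome regression for plant breeding
    populations structured as nested association mapping (NAM) designs. The
    package simulates multi-family backcross-selfing populations with known
    genetic ground truth, estimates variance components, broad-sense and
    genomic (SNP-based) heritabilities and per-genotype BLUEs from multi-year
    field trials, fits ridge-regression BLUP via Henderson's mixed-model
    equations and BayesB via a spike-and-slab Gibbs sampler, and evaluates
    predictors with family-stratified cross-validation, accuracy scaling,
    model comparison tests and predictor-reduction experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    lme4,
    data.table,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
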