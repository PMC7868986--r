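Package: hyblup
Title: Multi-Omic BLUP Hybrid Prediction with HAT Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts hybrid performance from parent-level multi-omic
    predictors (genome, transcriptome, metabolome, and parental phenome).
    Parent matrices are recoded into hybrid additive (mid-parent) and
    dominance (absolute parental difference) designs, per-layer kinship
    matrices feed a multi-kernel linear mixed model fitted by restricted
    maximum likelihood, and predictive ability is evaluated either by
    cross-validation or by an exact HAT-matrix leave-out method that avoids
    refitting. Nine models for incorporating parental phenotypic records as
    fixed covariates or a random kernel are provided, together with
    genome-wide ranking of all untested crosses, a synthetic-data simulator
    for recombinant inbred line populations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
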