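Package: epiridge
Title: Penalized Whole-Genome Regression with Pairwise Marker Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits additive and first-order epistatic whole-genome regression
    models (ordinary least squares, ridge-regression BLUP and its epistatic
    extensions with separate penalty factors for additive and interaction
    effects, and an l1-penalized LASSO variant) on allele-dosage marker data.
    Implements the polynomial translation theory behind marker-coding
    sensitivity: completeness checking of monomial sets, the exact coefficient
    transform induced by translating the marker coding, and degree-selective
    penalization that restores translation invariance.  Also provides additive
    and epistatic (Hadamard-product) relationship matrices, REML
    variance-component estimation for multi-kernel mixed models, a synthetic
    genotype/phenotype simulator, and an experiment harness for studying how
    the marker coding affects interaction-effect estimates, explained variance
    and out-of-sample prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
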