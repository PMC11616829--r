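Package: trioEMVS
Title: Joint Common and Rare Variant Selection from Case-Parent Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bayesian variable selection for disease-risk variants using
    phased case-parent trio genotypes. The affected child is contrasted with
    its three pseudo-siblings in a conditional logistic likelihood, and
    spike-and-slab priors with a dual region/variant indicator structure are
    fit by a deterministic-annealing EM algorithm, selecting individual
    common and rare variants jointly. Includes regularization-path tuning of
    the exclusion variances, a synthetic admixed-trio simulator with a
    logistic disease model and ascertainment on the affected child, and
    replicate-level evaluation metrics (weighted average correct association
    percentage, average true/false positive rates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'contrasts.R'
    'estep.R'
    'fit.R'
    'io.R'
    'metrics.R'
    'simulate.R'
    'tuning.R'
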