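Package: admixsel
Title: Admixture-Enabled Selection Scans in Admixed Populations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to detect and quantify post-admixture positive selection in
    a two-way admixed population. Provides a synthetic-data generator for a
    two-source admixture demography with recorded true local ancestry, a
    diploid hidden Markov model estimating local ancestry dosage from unphased
    genotypes, an ancestry-excess genome scan calibrated against neutral
    simulations (family-wise error rate and false discovery rate), f3 and
    f4-ratio admixture statistics with block-jackknife standard errors,
    rejection approximate Bayesian computation of a selection coefficient
    under a Wright-Fisher forward model, and two-locus linkage disequilibrium
    (D', r squared) from unphased genotypes via expectation-maximisation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
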