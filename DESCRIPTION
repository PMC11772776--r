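Package: argos
Title: Discovery of Amplification-Related Gain of Sensitivity (ARGOS) Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to identify genes whose expression is compensated under
    somatic copy-number gain and which are toxic when overexpressed
    (amplification-related gain of sensitivity, ARGOS). Implements a
    purity-aware Bayesian negative binomial regression of gene expression on
    DNA copy number (euploid-equivalent parameterization), significance-shrunk
    compensation scores, an ORF overexpression-screen depletion statistic,
    classification of compensated, hyperactivated, toxic and frequently
    amplified genes, protein-complex prioritization, and a seeded synthetic
    cohort generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
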