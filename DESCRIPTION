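Package: phenofix
Title: Detection and Correction of Misclassified Case/Control Phenotypes in GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian latent-variable modelling of differential
    phenotype misclassification in genome-wide association studies. A probit
    mixed model with kinship-structured random effects links genotypes at
    strongly associated (training) SNPs to a latent true phenotype; true- and
    false-positive recording rates are inferred by adaptive
    Metropolis-Hastings within Gibbs sampling, per-sample misclassification
    probabilities are averaged across iterations, flagged cases are switched
    to controls, and association analysis on the corrected phenotype surfaces
    supplemental candidate loci. Includes a liability-threshold case/control
    simulator with kinship random effects, an EMMAX-style linear mixed-model
    association scan, LD utilities, and ROC/PR benchmarking of both
    misclassified-sample detection and SNP detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
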