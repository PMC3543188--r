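Package: omixvar
Title: Bayesian Integrative Variance Partitioning of Genome and Transcriptome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint Bayesian whole-omics regression of a quantitative phenotype on
    pedigree, genome-wide SNP genotypes and whole-transcriptome abundances.
    Fits Bayesian mixed models (normal priors on all effect vectors) and
    Bayesian variable-selection models (two-component normal-mixture priors
    with inclusion indicators) by single-site Gibbs sampling, and partitions
    the posterior explained variance by data layer, by chromosome and by
    sliding SNP window.  Includes a pedigree module for the numerator
    relationship matrix and its sparse inverse, an F2-cross simulator with
    linked SNPs and eQTL-controlled expression probes, k-fold cross-validation
    of phenotype prediction, and MCMC chain diagnostics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
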