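Package: qtsmap
Title: Two-Step Mixed-Model GWAS for Epistasis and Gene-Environment
    Interaction in Recombinant Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps quantitative trait SNPs (QTS) in recombinant inbred line
    (RIL) populations evaluated in multiple environments, using a two-step
    strategy: an exhaustive generalized multifactor dimensionality reduction
    (GMDR) screen over 1-3 locus models nominates candidate SNPs, which are
    then tested by one- and two-dimensional mixed-linear-model scans with
    cofactor control and permutation-based experiment-wise thresholds, and
    all significant additive, epistatic, and gene-environment effects are
    jointly estimated by MCMC in a full hierarchical model with per-effect
    heritabilities. Includes a meiosis-based RIL genotype/phenotype
    simulator and a replicated power-study driver for validating the
    pipeline, plus readers for VCF and tabular genotype formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
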