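Package: pqtlstrat
Title: Protein Quantitative Trait Locus Scanning and Genotype-Stratified
    Subgroup Discovery for Complement Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for genotype-stratified analysis of circulating
    complement proteins in case-control cohorts: covariate screening,
    case-control protein association by linear and logistic regression,
    SNP-by-protein quantitative trait locus (pQTL) scanning with nested
    full-versus-reduced F-tests and Bonferroni correction, functional-group
    enrichment scoring of top hits, disease-overlap and effect-directionality
    analysis, and genotype-defined subgroup discovery via stratified ROC with
    a two-marker heterozygosity rule. Includes a synthetic genotype-phenotype
    cohort generator with planted effects for calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    mvtnorm,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
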