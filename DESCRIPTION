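Package: neutroqtl
Title: Cis-eQTL Mapping with Permutation Significance for Purified Immune Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for genome-wide cis expression
    quantitative trait locus (eQTL) analysis of purified immune cell
    transcriptomes. Provides a synthetic-data generator with known ground
    truth (linkage-disequilibrium blocks, minor allele frequencies,
    additive cis effects of controlled variance explained), microarray-style
    quality control and quantile normalization, additive linear-model
    association within a +/-250 kbp cis window with per-probe permutation
    significance thresholds, genotypic LD proxy expansion, cross-dataset
    eQTL sharing with hypergeometric enrichment, GWAS-catalog intersection,
    and genotype-stratified qPCR stimulation-response statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
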