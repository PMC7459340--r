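Package: radpop
Title: Population Genomic Diversity Analysis for RAD-Seq SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for analysing genomic diversity in crop
    germplasm panels genotyped with reduced-representation sequencing (ddRAD)
    SNPs. Reads multi-sample VCFs into a dosage matrix, applies staged quality
    filters (locus presence, minor allele frequency, missingness), computes
    per-locus and per-sample diversity statistics (PIC, Nei gene diversity,
    heterozygosity), estimates model-based ancestry by an EM admixture model
    with cross-validated choice of the number of populations, derives
    allele-sharing dissimilarities with Ward clustering, k-means/BIC cluster
    selection and principal-coordinate MDS, characterises linkage
    disequilibrium decay and performs LD pruning, screens for group-private
    alleles by minor-allele-frequency contrast, and selects diversity-
    maximising mini-core collections. Includes a structured genotype-panel
    simulator with known truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
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
    ape,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
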