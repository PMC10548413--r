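Package: climadapt
Title: Landscape Genomics and Epigenomics of Local Climate Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for landscape-genomic analysis of local
    climate adaptation in structured plant populations: per-population
    diversity statistics and Weir-Cockerham differentiation, principal
    coordinates analysis, Mantel and partial Mantel tests of isolation by
    distance and by environment, frequency-based ABBA-BABA introgression
    statistics with block-jackknife errors, a simulation-null FST outlier
    scan conditioned on heterozygosity, a kinship-corrected exact-spectral
    linear mixed model for methylation- and genotype-climate association
    with permutation significance thresholds, and gradient-forest turnover
    modelling with local and forward genomic-offset prediction under
    future climates. A synthetic-data generator reproduces the island-model
    population structure, climate gradients and methylation variation the
    analyses assume, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    geosphere
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    randomForest,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
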