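Package: qtlscan
Title: Whole-Genome QTL Scans by Haplotype, Mixed-Model and Bayesian Regression Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and comparison of three whole-genome quantitative trait
    locus (QTL) mapping strategies for livestock populations: a linkage
    disequilibrium and linkage analysis (LDLA) scan fitting a haplotype-cluster
    variance component per locus, an efficient mixed-model association (EMMA)
    scan with a genomic relationship matrix, and Bayesian variable-selection
    regression (BayesC) with per-SNP Bayes factors.  Includes a synthetic-data
    generator (pedigree designs, LD-structured founder haplotypes, gene
    dropping, phenotypes with a planted QTL), pedigree and genomic kinship
    matrices, a restricted maximum likelihood (REML) engine for variance
    components, pseudo-null significance thresholds, and power/FDR/localization
    scoring over factorial simulation grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
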