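Package: mirqtl
Title: Mapping and Multi-Omic Integration of Brain miRNA Expression
    Quantitative Trait Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for microRNA expression quantitative trait locus
    (miR-QTL) analysis: abundance filtering and TMM/log2-CPM normalization of
    small-RNA counts, surrogate-variable estimation, additive linear-model
    cis-QTL scans with Storey q-values, LD clumping and stepwise conditional
    analysis, single-causal-variant Bayesian colocalization, summary-based
    Mendelian randomization with the HEIDI heterogeneity test, FUSION-style
    miRNA-wide association (miRWAS) with a four-criteria causal screen,
    MAF-stratified Cochran-Mantel-Haenszel regulatory-region enrichment, and
    cross-study sharing statistics. Includes a seeded synthetic-data generator
    producing LD-structured genotypes, negative-binomial miRNA counts with
    planted cis effects, and GWAS summary statistics under mediated,
    pleiotropic, linkage and null scenarios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    edgeR,
    glmnet,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
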