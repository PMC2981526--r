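Package: aligator
Title: Pathway Enrichment Analysis of GWAS by SNP Resampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-set (pathway) enrichment analysis of genome-wide
    association studies driven by per-SNP summary statistics. Implements
    the ALIGATOR resampling scheme: a list of significant SNPs is
    converted into a list of significant genes and tested for
    over-representation in functional categories against replicate gene
    lists built by random SNP sampling, which corrects for variable
    numbers of SNPs per gene and for linkage disequilibrium. Also
    provides estimation of the effective number of independent SNPs and
    binomial tests for an excess of significant SNPs, cross-study
    replication and joint enrichment of categories, gene-wide and
    set-based phenotype-permutation tests (minimum p, average allelic
    chi-squared, Simes correction, rank-based gene-set enrichment), and
    a case-control GWAS simulator with block linkage disequilibrium and
    planted pathway effects for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
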