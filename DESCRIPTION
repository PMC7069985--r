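Package: haplometh
Title: Haplotype-Resolved Single-Cytosine Methylation Analysis of Long-Read
    Bisulfite Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for allele-specific methylation (ASM)
    analysis of targeted long-read bisulfite amplicon sequencing data.
    Provides dual-barcode demultiplexing with exact matching, read-quality
    filtering and deduplication, conversion-aware global alignment of
    bisulfite reads against amplicon references, per-read haplotype
    assignment directly from the sequencing data, per-cytosine methylation
    quantification with CpG-SNP masking and depth filtering, a full
    statistical battery for ASM and phenotype association (rank tests,
    per-site logistic regression, matched-pairs comparisons, cognition
    general linear models, Benjamini-Hochberg FDR), exploratory factor
    analysis with parallel analysis, a sparse Gaussian graphical model of
    site methylation selected by extended BIC, and difference-curve analysis
    for methylation-sensitive high-resolution melting (MS-HRM) validation.
    A synthetic-data generator emulates the full experimental design
    (amplicons with CpG/CpH sites and CpG-SNP markers, haplotype catalogs,
    case/control cohorts, barcoded bisulfite reads, melt curves) so the
    whole pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
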