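Package: h2scan
Title: Disease-Critical Cell Types from Single-Cell Annotations and
    Stratified LD-Score Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds SNP-level cell-type annotations from single-cell
    ATAC-seq peak sets (binary peak membership) and single-cell RNA-seq
    specific-expression gene scores linked to SNPs through enhancer-gene
    links or gene-body windows, then estimates each annotation's
    conditional contribution to disease heritability with stratified
    LD-score regression: per-annotation coefficients with block-jackknife
    standard errors, standardized effect sizes (tau-star), heritability
    enrichment, and one-sided p-values for positive tau-star.  A scan
    layer runs many GWAS traits against many cell types, excludes
    negative tau-star pairs, applies per-dataset Benjamini-Hochberg FDR,
    prunes genetically correlated traits, and computes concordance
    diagnostics.  A synthetic-data module generates LD-block-structured
    reference panels, annotations, GWAS summary statistics with the
    assumed heritability model, labeled expression counts with planted
    marker genes, and peak/link interval files, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
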