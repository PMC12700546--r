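Package: scherit
Title: Cell-Type-Resolved Heritability Enrichment from GWAS Summary
    Statistics and Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links genome-wide association summary statistics to cell types
    defined by single-cell transcriptomics or chromatin accessibility.
    Computes covariate-adjusted expression-specificity matrices and top-K
    marker gene sets, builds SNP annotations from gene sets or open-chromatin
    regions, runs stratified LD-score regression with block-jackknife
    standard errors to partition SNP heritability across cell types,
    computes gene-level association and heritability statistics with an
    LD-aware null, performs gene-property regression conditioned on average
    expression, and provides downstream statistics: dual-method concordance,
    hypergeometric over-representation, QQ-slope enrichment of perturbed
    gene sets, and pre-ranked gene-set enrichment. Ships a synthetic-data
    generator with known ground truth (block-LD panels, annotation-enriched
    summary statistics, clustered expression with donor covariates) and an
    end-to-end pipeline over plain-text file formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
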