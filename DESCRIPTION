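Package: methage
Title: Differential Methylome Analysis for Paternal-Age Bisulfite Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for two-group differential DNA-methylation
    analysis of bisulfite-sequencing count data, built around study designs that
    compare sperm or embryo methylomes from advanced-paternal-age and young
    donors. Reads Bismark-style coverage tables, applies per-CpG Welch/Student
    t-tests or pooled Fisher exact tests, calls directional differentially
    methylated regions (DMRs) by clustering significant CpGs within a fixed
    genomic window, annotates DMRs with CpG island/shore/shelf context, genes,
    cytobands and nucleosome-retention regions, computes Fisher odds-ratio
    enrichment statistics with Benjamini-Hochberg correction, localizes
    DMR-associated genes along chromosomes with bootstrap kernel density
    estimates, and provides hierarchical clustering, age regression and a
    450K-style beta-matrix adapter. A beta-binomial simulator generates
    datasets with spiked ground-truth DMRs and planted enrichments so every
    stage is testable without access to controlled human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    mclust,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
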