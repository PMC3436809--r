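Package: eqtlnet
Title: Association Gene Networks and Cohort Genotype Summaries for eQTL Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scriptable analysis of expression quantitative trait locus (eQTL)
    cohorts. Builds the gene-gene association multigraph implied by significant
    two-locus (epistasis) SNP-pair statistics, applies the single-locus
    R-squared/p filter cascade and edge-weight thresholding, maps SNPs to their
    nearest gene, summarizes case/control cohort genotypes into three-state
    consensus views with per-SNP Pearson chi-squared tests and a
    consensus-difference relevance rule, ranks genes by FDR-corrected
    differential expression, and renders static network, genotype-view and
    heatmap figures. Includes PLINK-style result-file parsers, mirror
    single-/two-locus regression scans for self-contained pipelines, and a
    seeded synthetic cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
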