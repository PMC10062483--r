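Package: gliaScore
Title: Glial Phenotype Signature Scoring for Developmental Ethanol
    RNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for bulk cerebellar RNA-seq studies of
    early postnatal ethanol exposure. Provides low-expression filtering,
    trimmed-mean-of-M-values (TMM) normalization factors and log2
    counts-per-million transformation; per-gene two-group linear models
    with empirical-Bayes variance moderation, moderated t-statistics and
    Benjamini-Hochberg adjustment; curated glial and cell-cycle
    phenotype gene-set catalogs with GMT import/export; the average
    z-score signature statistic with two-tailed Student's t group
    comparison; exploratory PCA, Pearson-correlation hierarchical
    clustering and volcano classification; and a seeded
    negative-binomial count simulator emulating a balanced
    two-treatment, two-timepoint, litter-structured study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    optparse,
    withr
biocViews: RNASeq, DifferentialExpression, GeneExpression,
    Normalization, GeneSetEnrichment, Transcriptomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
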