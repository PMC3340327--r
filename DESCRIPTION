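Package: apexdge
Title: Digital Gene Expression Analysis of Shoot Apex Transcriptomes
    Without a Reference Genome
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for tag-count digital gene expression (DGE) profiling
    against a de novo reference transcriptome, as used for crops that lack
    a reference genome.  Implements normalization to tags per ten million
    mappable reads, minimum-tag filtering, sample-level Pearson
    correlation with hierarchical clustering, principal component
    analysis, MA-statistic based two-group differential expression with a
    pooled-variance t-test, seed-locus co-expression screening, a
    multi-condition hormone-induction screen, transcriptome assembly
    summary statistics (N50, large-transcript classification), stringency
    filtering and overlap accounting for tabular BLAST output, and a
    negative-binomial count simulator with planted effects for validating
    every stage against a known truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
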