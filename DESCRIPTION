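Package: mirhostnet
Title: Tissue-Specific Functional Association Between Intronic miRNAs and
    Their Host Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for testing whether the predicted targets of an
    intronic microRNA are functionally associated with its protein-coding
    host gene in tissue-specific functional gene networks. Integrates
    miRNA target predictions across predictors and mature forms, filters
    targets through host-gene-centric network association scores,
    converts scores to fractional ranks, tests target/association-set
    overlap with the hypergeometric distribution, compares score and
    network-centrality distributions with rank-sum tests, and runs
    gene-set enrichment (over-representation and preranked running-sum
    modes) with false-discovery-rate control. Includes a synthetic-data
    generator with planted overlap depletion, centrality elevation and
    gene-set enrichment so every stage is testable without external
    database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
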