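Package: kgsa
Title: Keystone-Gene Group Significance Analysis for Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Network-based analysis of drug effects on transcriptome
    profiles with three experimental conditions (control, disease model,
    treated). Calls differentially expressed genes, derives the
    reverse-regulated gene set, builds a Pearson co-expression network
    with FDR edge filtering, ranks genes by PageRank centrality,
    characterizes network degradation under targeted attack to select
    keystone (hub) genes, detects functional groups on merged pathway
    graphs by leading-eigenvector modularity, and scores each group with
    a keystone-gene-based running-sum enrichment statistic whose
    significance is estimated by Monte Carlo simulation with
    Simes-Hochberg step-up adjustment. Includes a seeded synthetic-data
    generator with ground-truth labels so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    jsonlite,
    yaml,
    xml2,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
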