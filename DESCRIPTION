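Package: coevotree
Title: Organism-Set Sampling for Tree-Similarity Co-Evolution Analysis of
    Protein Interactions
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Pipeline for studying how the choice of reference organisms
    affects tree-similarity ("mirrortree") prediction of protein
    interactions. Implements taxonomy-based organism sampling ("nearest"
    and "level" criteria), reciprocal-best-hit orthology from BLAST
    tabular hit tables, neighbor-joining trees and patristic distance
    matrices, three co-evolution scorers (mirrortree, profile-correlation
    and context-mirror partial correlations), and coverage-aware ROC and
    F-measure evaluation against gold-standard interaction sets.  A
    synthetic-benchmark generator produces species trees, correlated
    gene-family distance matrices, taxonomies, hit tables and gold
    standards so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
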