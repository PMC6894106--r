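Package: lbdrank
Title: Hybrid Semantic Relatedness Ranking for Literature-Based Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ranks candidate biomedical entities (genes, drugs, diseases)
    by their relatedness to a target entity using a hybrid score that
    combines abstract-level co-occurrence statistics with embedding-derived
    semantic relatedness. Direct evidence is weighted by how often a pair
    repeats within single abstracts; hidden (indirect) evidence is
    accumulated over shared intermediate entities in the co-occurrence
    graph, following Swanson's ABC model of literature-based discovery.
    Includes trainable relatedness providers (skip-gram with negative
    sampling, thesaurus-specialized skip-gram, COALS, random indexing),
    ranked-retrieval evaluation utilities, and a synthetic corpus
    generator with planted direct and indirect structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
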