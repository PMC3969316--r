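Package: coauthnet
Title: Co-Authorship Network Analysis of Bibliographic Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and analyses co-authorship collaboration networks from
    structured bibliographic records, with an emphasis on international
    scientific collaboration between countries of different World Bank income
    groups. Provides corpus validation and normalization, author-level and
    country-level network construction with income-group mixing matrices,
    from-scratch implementations of the standard whole-network and per-node
    statistics (degree, betweenness, PageRank, density, clustering
    coefficient, path lengths, modularity and greedy community detection,
    discrete power-law fitting), Laplacian spectral clustering with eigengap
    model selection, collaboration-size and income-pairing summary tables, a
    small-world assessment against random-graph baselines, and a seeded
    synthetic corpus generator so the whole pipeline is testable without any
    external dataset. Graphs are exported to GraphML, GEXF and edge-list TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
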