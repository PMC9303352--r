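Package: assocnet
Title: Individual Semantic Networks from Free Association Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted, undirected semantic networks from per-participant
    free-association responses (cue plus up to three responses per encounter),
    quantifies their macroscopic structure (size, mean degree, local clustering,
    average shortest path length) and node-level properties (scaled PageRank
    centrality, Katz walk similarity with optional positive pointwise mutual
    information reweighting), and links those properties to performance in
    verbal-fluency, episodic free-recall and paired-associate tasks. Includes
    individual-versus-aggregate network comparison, repeat-encounter reliability
    statistics, a synthetic-cohort generator with group-structured ground-truth
    networks and behaviour coupled to centrality and similarity, and a single
    pipeline entry point that produces machine-readable result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
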