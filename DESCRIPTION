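Package: leprimalign
Title: Local Entropy-Based Alignment of Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise local alignment of weighted protein-protein interaction
    networks to predict evolutionarily conserved modules. Implements the
    LePrimAlign algorithm: a PageRank-style Markov-chain global alignment
    (PrimAlign) over the two interconnected networks, graph-entropy seed
    clustering, and greedy cluster-pair expansion under a match/gap local
    scoring scheme. Includes the standard evaluation metrics for conserved
    module prediction (best-match f-score against a complex catalog,
    inter-species semantic similarity, conserved edge counts, Jaccard
    overlap filtering) and a deterministic generator of paired synthetic
    networks with planted conserved modules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
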