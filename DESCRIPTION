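Package: learnNJ
Title: Learnable Neighbor Joining for Phylogenetic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end learnable neighbor-joining framework for
    phylogenetic tree inference from multiple sequence alignments. An
    axial-attention sequence encoder produces per-species, per-site
    representations; a tree decoder iteratively joins subtree pairs by
    learned priority scores, with greedy, Monte-Carlo and
    reinforcement-learning selection strategies. Includes supervised
    margin-ranking training with hard-negative selection, a GTR+I+G
    Felsenstein pruning likelihood, a sequence-evolution simulator
    (uniform random topologies, exponential branch lengths, GTR+I+G
    site evolution, deletion-induced gaps), the classical Saitou-Nei
    neighbor-joining baseline, and Robinson-Foulds evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
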