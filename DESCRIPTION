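Package: upm
Title: Frequent Probability-Pattern Mining in Uncertain Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines frequent probability patterns (candidate probabilistic
    motifs) in uncertain biological networks, i.e. graphs whose edges carry
    existence probabilities, such as confidence-scored protein-protein
    interaction or transcriptional regulatory networks. Connected non-tree
    k-node subgraphs are enumerated with an ESU-style algorithm, pairs of
    probability subgraphs are tested for probability isomorphism through the
    node voltages of their associated resistive circuits (edge probability =
    branch conductance, unit complete excitation, Hungarian assignment of
    voltage sequences), and the candidates are grouped into frequent patterns
    by a two-step hierarchical clustering. Includes a deterministic synthetic
    network generator with planted patterns and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    clue,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
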