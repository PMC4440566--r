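Package: cpedit
Title: Core-Periphery Decomposition of Protein Interaction Networks by
    Graph Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits protein-protein interaction networks to global
    core-periphery models by edge modification. Provides exact and
    simulated-annealing solvers for split cluster editing, monopolar
    editing, and cluster editing; certificate-producing recognition of
    split graphs and split cluster graphs; splittance from the degree
    sequence; enumeration of minimal forbidden induced subgraphs; seeded
    generators for Erdos-Renyi and planted core-periphery instances; and
    protein-complex detection statistics against a gold standard.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
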