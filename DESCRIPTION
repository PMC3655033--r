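Package: conformet
Title: Metric Filtering and 3D Embedding of Chromosome Conformation Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving spatial inconsistencies in chromosome
    conformation capture (3C/4C/Hi-C) interaction graphs. Detects violations
    of k-hop metric consistency (triangle-inequality violations and their
    longer-path generalization), selects maximum-confidence metrically
    consistent edge subsets with set-cover, hierarchical max-cut, shortest-path
    union and maximum-spanning-tree heuristics, bounds the optimum with a
    linear-programming relaxation, supports uncertain distance ranges via a
    slack factor, and evaluates filterings by stress-minimizing 3D embedding
    error and ensemble variability. Includes synthetic benchmark generators
    (planted point clouds, violation injection, an independent-set gadget)
    and TSV/JSON input-output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    boot,
    quadprog,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
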