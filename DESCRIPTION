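Package: dematelr
Title: DEMATEL Influence Analysis for Expert-Rated Factor Systems
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the Decision-Making Trial and Evaluation Laboratory
    (DEMATEL) method for structural analysis of interdependent factor
    systems rated by expert panels. Aggregates per-expert integer influence
    scores into a direct-relation matrix, normalizes by the maximum row
    sum, solves for the total-relation matrix T = X(I - X)^-1, derives
    prominence (R + C) and relation (R - C) statistics with cause/effect
    classification, and builds a thresholded causal influence digraph with
    DOT, GraphML and edge-list exports. Ships the 15-motivator
    family-physician-team study matrix as a worked fixture and includes a
    seeded synthetic expert-panel generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
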