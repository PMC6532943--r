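Package: petrigi
Title: Petri Net Exploration of Genetic Interaction Patterns in Gene
    Expression
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exhaustive enumeration and discrete Petri net simulation of
    three- and four-node gene regulatory motifs (two regulators, two
    downstream genes) to explain expression-based genetic interaction
    patterns, in particular inversion, where a gene moves in the opposite
    direction in a double deletion mutant compared to the single mutants.
    Includes the shared classifier that assigns buffering, quantitative
    buffering, suppression, quantitative suppression, masking and
    inversion calls to observed/expected log2 fold-change triples; survey
    analytics over the complete model space (stability filtering,
    pattern-by-complexity tables, co-pattern distributions, contingency
    tests, strong-weight sensitivity reruns); expression- and
    growth-based genetic interaction scoring of mutant-pair profiles with
    slow-growth signature correction, profile clustering and enrichment
    tests; and a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
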