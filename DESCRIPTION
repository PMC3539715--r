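Package: netpaleo
Title: Evolutionary Dating and Selection Analysis of Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers an upper bound on the evolutionary age of each edge of a
    human protein-protein interaction (PPI) network from ortholog
    presence/absence across eight mammals under a constrained single-appearance
    parsimony model, estimates Ks-calibrated interaction gain and loss rates
    with a steady-state correction, tests for co-evolution between interaction
    partners via correlated branch-wise selective constraint (mirrortrees),
    tests for shared directional selection on paired branches, and measures
    constraint and degree assortativity of the network against node-weight
    permutation and degree-preserving rewiring null models. Includes a
    synthetic-data generator that emulates every input with planted,
    recoverable parameters, hypergeometric gene-set enrichment with Bonferroni
    correction, and an end-to-end pipeline driver with deterministic seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
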