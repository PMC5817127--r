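Package: cophylotrack
Title: Event-Based Cophylogenetic Reconciliation and Clade-Rank
    Co-Phylogenesis Tests for Host-Associated Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tests whether a host-associated lineage tracked its hosts'
    phylogeny or shifted between hosts, using two complementary analyses:
    exact minimum-cost event-based reconciliation of a symbiont tree onto a
    host tree under a five-event model (cospeciation, duplication, host
    switch, loss, failure to diverge) with arbitrary event costs and a
    random-tip-mapping permutation null; and a Bayesian Poisson phylogenetic
    generalized linear mixed model regressing symbiont clade rank on host
    clade rank with a host-phylogeny-structured random effect, a host-genus
    random effect, observation-level overdispersion, and phylogenetic
    heritability. Includes joint host-symbiont simulators with known event
    ledgers for end-to-end validation, and a packaged host tree and
    specimen-association table for the Enchenopa binotata treehopper complex.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
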