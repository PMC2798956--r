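Package: lolcatSSA
Title: Exact Stochastic Simulation of Large Reaction Networks by Propensity Factoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An exact Gillespie stochastic simulation algorithm (SSA) engine for
    large mass-action reaction networks, implementing the LOLCAT Method: reaction
    propensities are factored over shared reactants into "clouds" backed by
    balanced k-ary cumulative-sum trees, the hottest reactions are kept in a
    linearly scanned super-cache, and post-firing updates are driven by a compact
    bipartite species/reaction dependency graph compiled into per-reaction update
    programs. Includes a textbook direct-method SSA oracle, an optimized-direct-
    method (ODM) baseline with operation counters, a synthetic hub-network
    generator, structural diagnostics (propensity-weighted valence CDFs, update-
    graph memory accounting), and a plain-text network format with restricted
    SBML ingest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
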