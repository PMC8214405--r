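Package: ppiresilience
Title: Protein Interactome Resilience under Long-Term Experimental Evolution
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study how the resilience of a protein-protein
    interaction (PPI) network changes as loss-of-function mutations
    accumulate during long-term experimental evolution. Provides network
    pruning from tabulated gene disruptions, a Monte-Carlo resilience
    statistic (one minus the mean normalized Shannon entropy of connected
    component sizes under random node failure), uniform and
    disruption-frequency-weighted randomization null models, exact
    signed-rank and rank-sum tests, single-gene disruption scans,
    essentiality diagnostics, a synthetic-experiment generator emulating a
    12-population evolution experiment, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
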