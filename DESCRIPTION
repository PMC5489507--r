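Package: netcoop
Title: Optimizing Scale-Free Network Structure for Cooperation in the
    Prisoner's Dilemma Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the Prisoner's Dilemma game on networks under three
    synchronous strategy-update rules (recolonization, Fermi, unconditional
    imitation) and evaluates the equilibrium cooperation level of a
    population structure.  Provides a multilevel evolutionary algorithm that
    rewires scale-free networks to raise their cooperation level without
    changing the degree sequence, using a hierarchical restoration-list
    memory to resist selection errors caused by noisy fitness, together with
    a clustering-coefficient baseline optimizer, scale-free generators
    (Barabasi-Albert and Holme-Kim), degree-preserving rewiring operators,
    and an experiment harness with tidy tabular outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
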