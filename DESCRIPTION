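Package: memlattice
Title: Payoff Memory in Spatial Evolutionary Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of two-strategy social dilemmas
    (prisoner's dilemma, snowdrift, stag-hunt) on a periodic square
    lattice in which a player's effective payoff incorporates its past
    payoffs, either as a geometrically weighted moving average or as a
    single probabilistically chosen delayed payoff.  Strategy updating
    follows asynchronous Fermi-rule imitation.  Includes T-S plane
    sweeps, prepared-domain fixation experiments, weak/strong subgroup
    classification, and invasion-rate ledgers between subgroups, with
    tidy tabular results and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
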