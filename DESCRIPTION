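Package: siteexposure
Title: Kinetics of Transcription Factor Binding Within Partially
    Unwrapped Nucleosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-molecule and ensemble FRET
    measurements of transcription factor binding at target sites inside
    nucleosomes through the Polach-Widom site-exposure mechanism.
    Implements the three-state kinetic model (wrapped, transiently
    unwrapped, unwrapped-and-bound) with its closed-form concentration
    dependences, exact stochastic simulation of FRET trace cohorts,
    two-state hidden Markov idealization, censored/truncated exponential
    dwell-time maximum likelihood, global fitting of transition rates
    versus ligand concentration, single- and two-event binding isotherm
    fitting, and construction of relative free-energy profiles of
    occupancy for comparison against a nucleosome unwrapping free-energy
    landscape.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
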