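Package: reusbind
Title: Replica-Exchange Umbrella Sampling Binding Free Energies for
    Host-Guest Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end replica-exchange umbrella sampling (REUS) pipeline for
    host-guest binding free energies on a tractable cylindrical toy model:
    Langevin sampling under harmonic umbrella biases and a flat-bottom
    cylindrical restraint, Metropolis window exchange, WHAM reweighting of the
    window histograms into a potential of mean force, standard-state volume and
    restraint-on (thermodynamic integration) corrections, stereoisomer
    averaging, a protonation-state thermodynamic-cycle pH correction, and the
    benchmark statistics (RMSE, Pearson r, Kendall tau, MAE/ME) used to score
    blind host-guest predictions against experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
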