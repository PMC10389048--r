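Package: beekin
Title: Artificial Bee Colony Optimization for Kinetic Parameter Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates kinetic rate-law parameters of ordinary differential
    equation models from concentration time series using the Artificial Bee
    Colony (ABC) metaheuristic. Bundles the glucose subsystem of the yeast
    (Saccharomyces cerevisiae) fermentation pathway (glucose influx and
    hexokinase rate laws), Simulated Annealing and Nelder-Mead simplex
    baseline optimizers behind a common contract, multi-run evaluation
    metrics (error rate, average error rate, STD), a seeded synthetic-data
    generator for fully self-contained benchmark problems, a profile-sweep
    identifiability check, and a small SBML import hook.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
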