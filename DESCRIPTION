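Package: refixr
Title: Refixation of Respiratory CO2 from Leaf Gas-Exchange Curves
Version: 0.1.0
Authors@R: person("refixr", "maintainers", email = "refixr@example.org",
    role = c("aut", "cre"))
Description: Estimates the parameters of the Farquhar-von Caemmerer-Berry
    model of C3 photosynthesis, including mesophyll resistance, from A/Ci
    gas-exchange curves by limitation-state segmentation and bounded
    nonlinear least squares, and derives the percentage of respiratory and
    photorespiratory CO2 refixed inside the leaf from a resistance-partition
    model. Includes a synthetic study generator emulating a multi-species,
    multi-season gas-exchange campaign, comparative statistics (two-factor
    analysis of variance, Tukey honest significant difference tests with
    compact letter displays, nested ordinary least squares models), a
    canonical CSV interchange format and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
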