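Package: beedar
Title: Doppler Radar Simulation and Classification of Honeybee Hive-Entrance Activity
Version: 0.1.0
Authors@R:
    person("beedar", "maintainers", email = "beedar@example.org", role = c("aut", "cre"))
Description: A physics-based simulator of 5.8 GHz continuous-wave IQ Doppler
    radar signatures of honeybee flights and environmental clutter at a hive
    entrance, together with the downstream analysis pipeline: fixed-grid window
    segmentation with flexible final overlap, Log Area Ratio feature encoding
    via linear predictive coding, hierarchical support vector machine
    classification of activity (inward, outward, hover, background) with
    Bayesian hyperparameter optimization, and benchmarking sweeps over sampling
    rate, coefficient count and sub-window size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
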