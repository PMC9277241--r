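Package: turbidive
Title: Underwater Visibility and the Foraging Behaviour of a Diving Seabird
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools linking the movement and diving
    behaviour of a pelagic pursuit-diving seabird to underwater visibility.
    Provides a seeded synthetic biologging generator (GPS tracks, time-depth
    records, gridded Secchi-disc depth, cloud and bathymetry fields with known
    ground truth), GPS track regularization and foraging-trip segmentation,
    dive and dive-bout detection with a two-process bout-ending criterion,
    solar geometry and gridded covariate annotation, a three-state hidden
    Markov movement model with turbidity-dependent transition probabilities,
    and penalized-spline mixed models of dive rate (negative binomial, AR(1)
    working correlation) and dive depth, together with an end-to-end pipeline
    that reports behavioural-state and visibility effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mgcv,
    geosphere,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
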