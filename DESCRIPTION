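Package: numerosense
Title: Emergence of Visual Number Sense in Generative Networks and Evolving Foragers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how an approximate
    number sense can emerge without number-specific supervision. Provides a
    generator of binary object-set images with exact control of numerosity,
    cumulative area, contour length and item size (including congruent and
    incongruent comparison pairs); a deep network with hard-wired on/off-centre
    spatial filters, an unsupervised generative (restricted Boltzmann machine)
    hidden layer and a delta-rule read-out for two-alternative numerosity
    comparison; psychophysical analyses (accuracy by numerical ratio, Weber
    fraction fitting, developmental trajectories, congruency costs); neuron-level
    coding analyses (summation-coding regression and two-factor ANOVA selectivity
    with tuning-curve pooling); and an artificial-life ecosystem in which
    recurrent-network foragers evolve quantity comparison under a genetic
    algorithm.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
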