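Package: unbindkit
Title: Ligand-Unbinding Kinetics Toolkit: Collective-Variable Discovery,
    String Free-Energy Profiles, and Machine-Learning Transition-State
    Analysis on Analytic Model Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for studying ligand-unbinding kinetics on
    analytic model potentials. Generates stochastic trajectories by
    overdamped Langevin dynamics on single-well, double-well and 2D
    pocket potentials; discovers distance-based collective variables by
    an iterative contact protocol under an incrementally ramped harmonic
    bias; refines unbinding paths with the finite-temperature string
    method and reconstructs potentials of mean force by binless WHAM;
    identifies the features that decide trajectory fate at the
    transition state with Machine Learning Transition State Analysis
    (MLTSA), ranking features by global-mean accuracy drop of a neural
    network and by gradient-boosted-tree importances; and converts
    between dissociation rates and activation free energies via the
    Eyring-Polanyi equation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
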