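Package: qgarbf
Title: Photosynthetic Rate Prediction with QGA-Optimised Radial Basis
    Function Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts leaf net photosynthetic rate from temperature, photon
    flux density and blue-light ratio with a radial basis function (RBF)
    regression network whose spread hyperparameter is selected by a quantum
    genetic algorithm (QGA). Includes a seeded synthetic gas-exchange data
    generator built on the non-rectangular hyperbola light-response curve,
    Dixon Q-test gross-error filtering, min-max normalisation and train/
    verification splitting, a generalized regression neural network (GRNN)
    baseline, a classical binary genetic algorithm, spread-sweep and
    six-model comparison harnesses, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
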