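Package: neuroloop
Title: Simulation and Neural-Network Control of Stimulation-Evoked Dopamine Release
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seedable simulator and analysis pipeline for neurochemically
    driven closed-loop deep brain stimulation. Provides a kinetic plant model
    of stimulation-evoked striatal dopamine release with fast-scan cyclic
    voltammetry measurement, a stimulation-protocol runner, a 12-coefficient
    (7th-degree polynomial rise plus biexponential decay) parameterization of
    evoked responses, Levenberg-Marquardt training of feedforward neural
    networks for forward (stimulus to response) and inverse (response to
    stimulus) models, energy-constrained stimulus optimization, and
    closed-loop performance evaluation with regression diagnostics and plots.
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
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
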