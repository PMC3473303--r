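Package: trustgame
Title: Trust-Game Decision Analysis of Clinical-Trial Participation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the decision to enroll in a randomized controlled trial
    as a trust variant of the prisoner's dilemma between a patient and a
    researcher. Provides closed-form expected utilities for the patient's
    trust/no-trust and the researcher's honor/abuse strategies with
    regret- and guilt-adjusted payoffs, an equipoise randomization model,
    threshold solvers and two-way sensitivity sweeps over the strategy
    regions, and a seeded Monte Carlo probabilistic-sensitivity engine
    that tabulates the joint distribution of optimal strategies. Includes
    a command-line interface for solving, threshold analysis, parameter
    sweeps and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
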