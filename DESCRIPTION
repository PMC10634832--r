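Package: flexshift
Title: Simulation and Analysis of Feature-Based Reversal Learning and Neural Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying attentional set shifting with feature-based
    colour-reversal tasks. Simulates the two-stimulus reversal task and a
    feature-value reinforcement-learning agent, fits the agent model by
    maximum likelihood and extracts latent variables (values, choice
    probability, reward prediction errors), estimates per-trial learning
    curves and statistically defined learning trials with an EM
    ideal-observer state-space model, generates ground-truth Poisson spike
    trains and two-class spike waveforms, classifies units into narrow- and
    broad-spiking classes, and runs the neural encoding battery: per-variable
    firing-rate regressions, permutation comparisons between recording
    conditions, best-variable rankings, and interspike-interval statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
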