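Package: contextreset
Title: Temporal-Context Reset Modelling of Event Boundaries and Temporal Order Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a binary temporal-context signal that drifts over a
    36-item list and resets at event boundaries by reinstating a proportion of
    the first context, and turns the simulated trajectories into
    recency-judgment predictions via a Dice-dissimilarity memory index.
    Encodes the boundary schedules and probe-pair tables of four list-learning
    experiment designs, sweeps the drift and reset rates over a grid with an
    effect-recovery criterion, fits model outputs to group behavioural means
    with linear and mixed models, runs the matching repeated-measures test
    battery (Greenhouse-Geisser corrected ANOVAs, paired t-tests, FDR), and
    generates synthetic subject-level accuracy tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    lme4,
    lmerTest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
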