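Package: fearreplay
Title: Replay-Based Reinforcement Learning Analysis of Two-Day Differential
    Fear Conditioning with Skin Conductance Read-Outs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for two-day differential fear
    conditioning and extinction studies read out through skin conductance
    responses (SCRs). Generates the constrained two-day trial paradigm
    (habituation, acquisition, extinction, recall), simulates phasic
    electrodermal traces with known ground truth, scores event-related SCRs
    by trough-to-peak detection with amplitude and rise-time criteria, and
    fits a value-learning agent trained by prioritized experience replay
    with a between-day sleep-replay phase to group-averaged SCR curves via
    a penalized grid search. Model-derived trial-by-trial predictions and
    absolute prediction errors can be exported as FSL three-column EV
    parametric-modulation regressors. Includes rank-based nonparametric
    repeated-measures statistics (ANOVA-type statistic with infinite
    denominator degrees of freedom, relative treatment effects, and
    Tukey-Kramer adjusted post hoc cell contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
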