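Package: dyadgame
Title: Quadratic Games and Bayesian Partner Models for Dyadic Joint Action
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of sensorimotor joint action in dyads.
    Joint tasks are expressed as quadratic games with discrete strategy
    choices; each player predicts the partner's next action with a trial-wise
    Kalman filter and selects strategy and action from a Boltzmann (softmax)
    distribution over expected cost with geometric temperature decay, yielding
    fictitious-play learning over repeated trials. Includes scenario builders
    for a spatial Stag Hunt and a two via-point reaching game (polyharmonic
    spline trajectories, Bryson-weighted costs, linear body dynamics),
    behavioral coordination metrics (minimum via-point distance, strategy and
    collaboration classification, leadership index), and maximum-likelihood
    identification of per-player behavioral parameters from action series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
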