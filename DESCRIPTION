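Package: gaitfog
Title: Basal Ganglia and Central Pattern Generator Simulation of Gait Through Doorways
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates doorway-induced gait changes in Parkinson's disease with a
    two-level motor-control model. The higher level is an actor-critic
    reinforcement-learning model of the cortico-basal-ganglia system: a 50-sector
    binary view vector of the doorway drives a tanh value function trained by
    temporal-difference error (the dopamine correlate, clamped to simulate
    dopamine-deficient OFF and medicated ON states), and a GO/EXPLORE/NOGO policy
    performs stochastic hill climbing over the value landscape to emit a velocity
    command. The lower level is a central pattern generator built from pools of
    adaptive Hopf oscillators that learn hip and knee joint-angle rhythms from
    teaching signals; a velocity-dependent gain modulates the learned oscillation
    amplitudes, and a kinematic leg model converts hip-angle extrema into stride
    and step lengths. Tools are provided to train agents under control and
    parkinsonian parameter presets, run doorway-approach trials, build normalized
    velocity profiles, and compute stride/step-length statistics including
    step-length variability and group comparisons.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    deSolve,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
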