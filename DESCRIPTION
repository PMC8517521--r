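Package: illnesschain
Title: Discrete-Time Markov Chain Analysis of Illness-State Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the post-diagnosis illness trajectory of pediatric
    sepsis as a discrete-time Markov chain over illness states obtained by
    binning a continuous sepsis risk score. Provides a synthetic-cohort
    generator with known transition kernels, risk-score discretization and
    adjacent-pair extraction, estimation of row-stochastic transition
    matrices with and without death as an absorbing state, Shannon entropy
    of the joint transition distribution, trajectory simulation, mean first
    passage times, stratified analyses, and time-window and binning
    sensitivity checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
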