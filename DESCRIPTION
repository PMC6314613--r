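Package: ipdbox
Title: Simulation and Strategy Inference for Iterated Prisoner's Dilemma
    Operant Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for operant-conditioning experiments in which an animal
    plays the iterated Prisoner's Dilemma against a Tit-for-Tat opponent for
    pellet rewards and timeout punishments. Provides a trial-level game
    engine with configurable payoff matrices and session timing, memory-one
    stochastic and named deterministic agent policies, estimation of
    transition vectors and outcome-state occupancy from session logs, the
    induced four-state Markov chain and its stationary distribution,
    payoff-matrix contrast analysis with best-strategy economics and
    normalized reward, a simulated-population reward/timeout baseline with a
    fitted separation line, thin contracts over the standard statistical
    tests used in such studies, and a synthetic-cohort generator covering
    acquisition, stability, reversal and matrix-switch phases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
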