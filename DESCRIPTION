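Package: prlewa
Title: Reversal Learning and Goal-Directed Action: Simulation, Modelling
    and Subgrouping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying goal-directed action and probabilistic
    serial-reversal learning. Provides generative task environments for an
    11-stage serial-reversal task and an outcome-devaluation procedure,
    experience-weighted attraction (EWA) and reward/punishment
    reinforcement-learning models with maximum a posteriori fitting and
    parameter-recovery diagnostics, model-free behavioural metrics
    (trials to criterion, perseveration, win-stay/lose-shift, devaluation
    response bias), hierarchical-clustering subgrouping of cohorts into
    intact and impaired goal-directed action, a parameter-substitution
    simulation study with Dunnett many-to-one comparisons, and a synthetic
    cohort generator so the full pipeline runs without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mvtnorm,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
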