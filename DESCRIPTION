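Package: poporl
Title: Developmental Modelling of Play-or-Pass Iowa Gambling Task Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying reinforcement learning on the play-or-pass
    variant of the Iowa Gambling Task across adolescent development. Simulates
    the task environment (deck payout schedules, fixed presentation and
    outcome sequences, bank accounting, play/pass/timeout semantics), fits the
    four-parameter play-or-pass outcome-representation learning (PoP-ORL)
    model to session logs with hierarchical empirical-Bayes shrinkage,
    validates fits with parameter-recovery and posterior-predictive-check
    harnesses, scores sessions with traditional proportion-play summaries, and
    estimates developmental trajectories of every performance metric with
    multilevel growth models including a familial depression-risk moderator.
    Ships a synthetic accelerated-longitudinal cohort generator (two
    recruitment cohorts, five waves, attrition, covariates) for end-to-end
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
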