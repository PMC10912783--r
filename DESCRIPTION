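Package: sborg
Title: Simulation and Hierarchical Bayesian Modeling of the
    Sure-Bet-or-Gamble Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates the Sure-Bet-or-Gamble (SBORG) risky decision-making
    task and synthetic cohorts of task-performing agents, builds the
    trial-history regressors of the momentary-happiness model with
    exponential forgetting, fits that model hierarchically (simultaneous
    individual- and group-level parameters) by MCMC, fits the trial-level
    logistic gamble-choice model per participant, and compares group-level
    posteriors via highest density intervals, difference distributions,
    Cohen's d effect sizes, and credible-difference fractions.  Includes
    descriptive evaluation (gamble rates with nonparametric tests,
    model-fit r-squared), delimited-text session I/O, and a seeded
    end-to-end pipeline for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    rjags,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
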