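Package: ermab
Title: Equitable Restless-Bandit Planning for Digital Health Outreach
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Plans monthly outreach interventions for a digital type-2-diabetes
    program using an equitable restless multi-armed bandit framework. Patients
    are modelled as independent Markov decision processes over joint
    engagement, clinical (HbA1c) and memory states, with a three-month delayed
    intervention effect and a belief-state treatment of the intermittently
    observed clinical dimension. Provides finite-horizon dynamic programming,
    the Whittle-index policy, per-group Lagrangian value functions, maximin
    (water-filling) and maximum-Nash-welfare budget allocators,
    standard-of-care baselines, a staggered-enrollment cohort simulator, and
    equity metrics (Gini coefficient, mean absolute difference), Pareto and
    capacity-planning analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
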