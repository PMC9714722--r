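Package: persuadeRL
Title: Personalized Reinforcement Learning for Persuasive Message Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and evaluating tabular reinforcement-learning
    algorithms that choose persuasive message types (commitment, consensus,
    authority, action planning, or no persuasion) in digital behavior-change
    interventions. Implements an effort-based reward on [-1, 1], similarity-
    weighted estimation of reward and transition functions over a binarized
    COM-B state space, value iteration, and four nested policy complexity
    levels (overall best action, best action per state, best Q-value, best
    similarity-weighted Q-value). Includes a synthetic-cohort simulator
    emulating a longitudinal persuasion-log schema, a resampled policy-
    agreement analysis based on Cohen's kappa, and Monte-Carlo power and
    regression sample-size calibration utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
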