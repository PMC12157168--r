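Package: formbo
Title: Bayesian Optimization and Machine Learning for Formulation Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for machine-learning-guided development of biopharmaceutical
    formulations. Implements Gaussian-process surrogate regression with a
    Matern 5/2 kernel, lower-confidence-bound acquisition with
    exploration/exploitation presets, tree-ensemble and linear surrogate
    models with fixed screening-scale hyperparameters, cross-validation and
    holdout evaluation, Shapley-value, permutation and wrapper feature
    attribution, an iterative experiment-suggestion campaign loop, and
    response-surface maps with optimal-zone extraction. Ships synthetic
    ground-truth landscapes emulating a liquid live-virus formulation screen
    (infectious titer loss) and a freeze-dried formulation screen (glass
    transition temperature of the freeze concentrate), so the full workflow
    can be exercised and tested without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lhs,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
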