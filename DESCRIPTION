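Package: uqreferral
Title: Predictive Uncertainty and Referral Learning for Binary Clinical
    Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies predictive uncertainty of binary classifiers from
    Monte-Carlo predictive samples (predictive entropy, expected entropy,
    mutual information, variation ratio, and the law-of-total-variance
    decomposition into epistemic and aleatoric parts), provides small
    reference Bayesian deep-learning samplers (Monte-Carlo dropout, deep
    ensembles, and a mean-field variational final layer trained by ELBO
    maximisation), models inter-annotator disagreement as human
    uncertainty, and implements referral learning: strategies that decide
    which instances a model should hand to a human expert, evaluated via
    referral curves against random and oracle baselines. Includes
    synthetic-data generators emulating the statistical structure of
    clinical text corpora so the full pipeline runs without access to
    credentialed data, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
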