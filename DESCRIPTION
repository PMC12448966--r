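Package: sofcpm
Title: Speed-of-Forgetting Phenotyping and Connectome-Based Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates an individual speed of forgetting from adaptive
    paired-associate learning data using a power-law trace-decay model of
    declarative memory, and predicts this phenotype from resting-state
    functional-connectivity features. Includes an adaptive fact-learning
    session simulator with continuous per-item decay estimation, model-fit
    diagnostics (binned response-time KL divergence and chi-square),
    Pearson and partial-correlation connectomes over a 17-network cortical
    parcellation with Fisher-z group averaging, an L1-penalized regression
    pipeline with leave-one-out lambda selection and a full validation
    battery (held-out prediction, feature-removal refits, variance
    inflation factors, permutation nulls), network-importance summaries,
    and synthetic-cohort generators with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    car,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
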