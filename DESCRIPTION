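Package: contextlearn
Title: Hierarchical Bayesian Learning Models and Psychophysics for
    Context Sensitivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying sensitivity to temporal and spatial
    context in human behaviour. Implements a probabilistic associative
    learning task generator with volatile and stable contingency phases;
    trial-wise belief filters for four learning models (three-level and
    two-level hierarchical Gaussian filters, Rescorla-Wagner, and Sutton
    K1); a linear response model mapping beliefs to log reaction times;
    per-subject MAP estimation with Laplace model evidence; random-effects
    Bayesian model selection with exceedance probabilities; a tilt-illusion
    psychophysics pipeline (1-up-2-down staircase, logistic psychometric
    fitting with parametric bootstrap and Monte-Carlo goodness of fit);
    dynamic learning-rate phase analysis; and a synthetic-cohort simulator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
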