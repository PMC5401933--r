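Package: mobaft
Title: Model-Based Recursive Partitioning with Parametric Accelerated
    Failure Time Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits parametric accelerated failure time (AFT) survival models
    under exponential, Weibull, log-logistic and lognormal distributions to
    right-censored data, and grows model-based recursive partitions with an
    AFT model in every node: parameter stability is tested along each
    partitioning covariate with score-based fluctuation statistics and
    permutation p-values, the most unstable covariate is split at the
    likelihood-optimal cutpoint, and the procedure recurses. Includes a
    synthetic right-censored cohort generator with configurable covariate
    marginals and latent subgroup structure, likelihood-ratio and AIC model
    comparison across parametric and tree models, tree export as structured
    text and DOT, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
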