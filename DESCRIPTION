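Package: bayesrep
Title: Bayesian Analysis of Internal Replication and Independent
    Replication Success
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether effects that were internally
    (conceptually) replicated in their original publication are more
    likely to survive independent, direct replication.  Provides
    Dirichlet-multinomial (Gunel-Dickey style) Bayes factors for 2x2
    contingency tables with one-sided (order-restricted) variants and
    Beta-posterior estimation of log odds ratios and proportion
    differences; Jeffreys-Zellner-Siow default Bayes factors for
    two-group mean differences; robust Bayesian estimation of group
    differences under a t likelihood; generative simulations of
    questionable research practices (optional stopping, publication
    bias, HARKing); and a synthetic study-table generator that emulates
    a reproducibility-project-style dataset under competing accounts of
    replication failure, so the full analysis pipeline can be exercised
    end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
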