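Package: paleoneuro
Title: Comparative Paleoneurology of Encephalization, Hearing and
    Vestibular Scaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative comparative paleoneurology of fossil
    archosaurs. Computes reptile encephalization quotients from endocast
    volumes with endocranial-fill and tissue-density conventions and
    interval propagation of body-mass uncertainty; estimates hearing
    ranges from endosseous cochlear duct dimensions via best-frequency
    and basilar-papilla scaling relationships; and derives olfactory and
    semicircular-canal ratio statistics. Trait allometries are fitted by
    phylogenetic generalized least squares with maximum-likelihood
    estimation of Pagel's lambda, run across ensembles of time-calibrated
    trees with best-iteration, median and residual-distribution
    summaries. A synthetic-data generator (pure-birth trees, Brownian
    traits under a lambda-distorted covariance) supports desk-scale
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
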