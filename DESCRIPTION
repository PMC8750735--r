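Package: mbil
Title: Markov Blanket and Interactive Risk Factor Learning for Discrete Clinical Data
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Score-based learning of single and interactive (nonadditive) risk
    factors of a binary clinical outcome from a table of categorical variables.
    Implements the Bayesian Dirichlet equivalent uniform (BDeu) family score
    with a tunable prior equivalent sample size (alpha), exhaustive interaction
    detection over small variable sets, greedy Markov-blanket search for the
    outcome's direct risk factors, a planted-effect synthetic cohort generator
    for validation, and a reporting layer producing partner-frequency tables
    and causal-set listings. Ships a 31-variable breast-cancer metastasis
    schema and supports running the full pipeline across several outcome
    horizons and alpha values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
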