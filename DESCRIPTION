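Package: testcross
Title: Line-by-Tester Combining Ability Analysis for Multi-Environment
    Testcross Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of incomplete line-by-tester testcross
    trials evaluated across managed-stress and optimum environments, as used
    in maize hybrid breeding. Provides plot-level trait derivation (grain
    yield from field weight and moisture, anthesis-silking interval),
    crossing-plan construction and connectivity checks, REML variance
    component estimation for the stage-wise mixed models of multi-environment
    trials, broad-sense heritability, general and specific combining ability
    (GCA/SCA) effects with significance tests, Baker's ratio, proportional
    genetic contributions, trait-trait correlations, GCA-based hybrid
    prediction with leave-one-hybrid-out cross-validation, and a synthetic
    trial generator that emulates the statistical structure of an
    alpha-lattice line-by-tester experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
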