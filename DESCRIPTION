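Package: aeroscope
Title: Thermal Performance, Aerobic Scope and Environmental Association
    Analysis for Fish Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for interpopulation thermal-physiology
    experiments on juvenile fishes. Converts intermittent-flow respirometry
    oxygen-saturation traces into routine and maximum metabolic rates and
    aerobic scope with the standard quality-control rules; fits Bayesian
    Gaussian mixed models for growth rate, critical thermal maximum and the
    three metabolic traits with WAIC-based stepwise selection; derives
    treatment marginal means, pairwise posterior contrasts, acclimation
    capacities and thermal optima (the temperature maximizing aerobic scope)
    from posterior draws; and screens associations between population-level
    environmental predictors and each trait, including test-temperature
    interactions and leave-one-population-out robustness. A synthetic-data
    generator emulates the full study design with known ground truth so every
    stage is testable without raw field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
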