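Package: forestcl
Title: Regional Tree Growth and Survival Responses to Nitrogen and Sulfur
    Deposition, with Critical Loads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-stage analysis of forest-inventory tree demography along
    atmospheric deposition gradients. Stage one fits nonlinear growth and
    survival dose-response models (lognormal climate and nitrogen modifiers,
    sigmoid or lognormal sulfur terms) per species and ecoregion Division by
    maximum likelihood with simulated annealing, selects among candidate
    model families by AIC with a nitrogen-sulfur collinearity exclusion
    rule, classifies the fitted response-curve shapes on an ordered
    vulnerability scale, and inverts the fitted curves into critical loads
    (kg ha-1 yr-1). Stage two models the ordinal vulnerability of those
    shapes against climate, soil pH, deposition and functional-trait
    covariates with proportional-odds regressions and stepwise AIC
    selection, plus Fisher exact tests, one-way ANOVA with Tukey HSD, and a
    Blomberg's K phylogenetic-signal check. A synthetic-data module
    generates forest-inventory-like tree records from the same model
    equations with known parameters so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phytools,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
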