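Package: rabswitch
Title: Structural Identification of the Rab5-Rab7 Conversion Switch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated structural identification of kinetic models of the
    Rab5-Rab7 conversion switch in early endocytosis. Enumerates a
    combinatorial library of candidate ordinary-differential-equation model
    structures (alternative GEF and GAP kinetic laws), estimates the
    parameters of every candidate by Differential Evolution against
    fluorescence time-series data, ranks the candidates under
    domain-independent and domain-specific model-selection criteria
    (relative error, hidden-state correlation, switch-time displacement, and
    complexity trade-offs), detects indistinguishability plateaus in the
    error profile, and assesses practical parameter identifiability by
    bootstrap refitting on noise-perturbed data. Includes a synthetic-data
    generator that emulates the limited observability of the experimental
    system (only scaled totals of active- and passive-state protein
    concentrations are observed).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
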