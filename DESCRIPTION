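Package: leaftherm
Title: Leaf Energy Balance and Thermoregulation from Canopy Microclimate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing leaf thermoregulation in forest canopies from
    microclimate time series and leaf traits. Implements a steady-state leaf
    energy balance driven by radiation, boundary-layer and stomatal
    resistances, its inversion for boundary-layer resistance, nonlinear
    recalibration of the boundary-layer conductance against wind speed and
    leaf width, species-level stomatal responses to vapour pressure deficit
    fitted as linear mixed models with leaf-level random intercepts, leaf
    thermal time constants from structural traits, a windowed
    regression-based data-selection filter that certifies radiation
    measurements represent the leaf surface, species contrasts under matched
    microclimate, and trait-substitution counterfactuals. A seeded synthetic
    canopy-microclimate generator reproduces the statistical structure the
    analysis assumes so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    e1071,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
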