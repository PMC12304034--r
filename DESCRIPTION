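Package: heatward
Title: Heat Tolerance and Thermoregulatory Analysis for Heterothermic Endotherms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying thermoregulation in the heat for small
    heterothermic endotherms. Detects torpor bouts and classifies active
    versus passive arousals from skin-temperature telemetry, reduces
    flow-through respirometry traces to whole-animal metabolic rate,
    evaporative water loss and the ratio of evaporative heat loss to
    metabolic heat production, and estimates thermoregulatory inflection
    points with segmented linear mixed-effects models (random intercept per
    individual) including segmented-versus-linear model selection,
    confidence-interval comparison of breakpoints between groups, backward
    model reduction and estimated marginal means. A synthetic-data module
    generates telemetry traces, raw gas-analyser trials and calibration
    tables with known ground truth so the full pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nlme,
    emmeans,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
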