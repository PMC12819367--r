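Package: heatadapt
Title: Urban Heat Adaptation Scenarios and Heat-Attributable Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Health-impact analysis of urban heat adaptation strategies on a
    synthetic city. Generates Local Climate Zone (LCZ) maps, morphology,
    population, gridded daily temperature fields, crowdsourced-style station
    observations and quasi-Poisson daily mortality; applies adaptation
    scenarios (cool roofs, relative greening, rural replacement) as
    morphology transforms; learns a spatially explicit morphology-driven
    bias correction for daily maximum temperature and propagates scenario
    deltas unchanged; computes population-weighted heat-exposure statistics
    stratified by LCZ; and fits a spline exposure-response curve with a
    minimum-mortality temperature to estimate heat-attributable deaths with
    Monte-Carlo confidence intervals and scenario comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    MASS,
    glmnet,
    randomForest,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
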