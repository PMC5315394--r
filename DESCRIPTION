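Package: spatcc
Title: Spatial Exposure Assessment and Matched Case-Control Analysis on
    Synthetic Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Residential proximity exposure assessment and matched
    case-control analysis for spatial epidemiology: crop area-fraction
    indices in circular buffers around residences, five-category
    industrial/urban/rural environment classification with a
    distance-threshold sensitivity sweep, census-tract socioeconomic
    quartiles, 6:1 individual matching on sex, birth year and region, and
    mixed-effects unconditional logistic regression odds ratios.  Includes
    a synthetic-landscape and population simulator with a configurable
    logistic outcome model for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lme4,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
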