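Package: dielflux
Title: Diel Partitioning and Temperature-Response Analysis of Continuous Soil Respiration Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous chamber-based soil CO2 efflux time
    series on the day-night (diel) cycle. Splits hourly flux records into
    daytime and nighttime using solar geometry, applies a quality-control
    cascade for chamber data, fits period-specific exponential temperature
    responses (Q10), temperature-adjusts fluxes to a common reference,
    quantifies the bias of predicting nighttime fluxes from daytime
    temperature relationships, attributes that bias to root versus
    heterotrophic components, and relates fluxes to gross primary
    productivity through standardized major axis regression and lagged
    correlation profiles. Includes a mechanistic synthetic-data generator
    with a photosynthate substrate-supply lag so that every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm
Config/testthat/edition: 3
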