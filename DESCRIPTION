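Package: thermocomm
Title: Community Temperature Indices and Altitude-Standardized Thermal Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying short-term thermophilization of species
    communities along elevational gradients from repeat presence/absence
    surveys. Computes the community temperature index (CTI, mean of member
    species temperature indices) and community temperature variation (CTV,
    their standard deviation), converts temporal index changes into metres of
    equivalent altitudinal displacement via the group-specific CTI-altitude
    slope, models the standardized shifts against polynomial altitude with
    species-richness-dependent residual variance (generalized least squares
    with fixed, power, and constant-plus-power variance functions, AIC
    variance-structure and backward fixed-effect selection, REML likelihood
    ratio tests, and nonparametric case-resampling bootstrap intervals), and
    tests altitude-dependence of air-temperature trends with a crossed
    random-intercept mixed model. Includes a synthetic-data generator that
    emulates a national biodiversity monitoring design (Gaussian species
    response curves on an elevational gradient, imposed altitude-dependent
    community shifts, station temperature series) so the full pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
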