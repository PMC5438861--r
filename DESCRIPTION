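Package: sadcwc
Title: Stock-and-Flow Modelling of the Substance-Abuse and Drug-Related-Crime Syndemic in the Western Cape
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and scenario analysis for the SADC-WC compartmental
    stock-and-flow model of substance abuse and drug-related crime in the
    Western Cape province of South Africa. Provides a generic fixed-step
    stock-and-flow integrator with per-step outflow limiting, the five-stock
    SADC-WC model (community, abusers, correctional services, rehabilitation,
    law-enforcement case load) with its printed flow equations, anchored
    geometric reconstruction of the exogenous rehabilitation-uptake and
    crime-case series, bounded calibration of the estimated parameters,
    hindcast and projection scenarios, and three policy-intervention
    experiments with linear parameter ramps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
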