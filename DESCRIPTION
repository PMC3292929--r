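Package: AccessBurden
Title: Travel-Time Accessibility Surfaces and Distance-Decay Models of
    Health Facility Utilisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for national-scale healthcare-accessibility analysis on
    gridded landscapes. Builds per-pixel friction ("cost") surfaces from
    land cover, road and river layers with slope-dependent walking speeds,
    accumulates multi-source least-cost travel times to health facilities,
    fits a three-parameter logistic distance-decay model of public-facility
    attendance for childhood fever against travel time, delineates facility
    catchments under a travel-time threshold, and estimates the number of
    fever cases among children under five likely and unlikely to be treated
    in the public sector. Includes a synthetic-landscape simulator that
    emulates the survey and raster structure the analysis assumes, so the
    whole pipeline is testable without confidential survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
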