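Package: wearpm
Title: Personal Particulate-Matter Exposure Analysis from Wearable Sensor Traces
Version: 0.1.0
Authors@R:
    person("wearpm", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing minute-resolved personal PM2.5/PM10 exposure
    collected with GPS-enabled wearable monitors in school-age cohorts.
    Provides trace ingestion and quality control (continuous-validity and
    GPS-gap filters), geofence-based microenvironment tagging (home, school,
    commute), exposure summarisation (daily means, microenvironment and
    diurnal profiles, PM2.5:PM10 coarse-fraction ratios, WHO 24-h guideline
    exceedance), a nested random-intercept log-linear mixed model of exposure
    determinants with Satterthwaite degrees of freedom and percent-change
    reporting, rank-based group tests (Kruskal-Wallis with Dunn-Holm
    post-hocs), and a fully seeded synthetic cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    lme4,
    Matrix,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
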