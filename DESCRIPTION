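Package: sccbb
Title: Single-Cell Cultivation Planning and Sequential Design-of-Experiments
    Optimization for Biosurfactant Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational chain behind single-cell-based
    high-throughput cultivation and functional screening of
    biosurfactant-producing bacteria: Poisson occupancy models for planning
    limiting-dilution inoculation of microplates (blank-fraction targets,
    dilution series, lambda calibration with exact confidence intervals,
    culture-purity prediction), bookkeeping and diversity summaries for
    plate screens and isolate collections, Plackett-Burman screening designs
    with main-effect t-tests, steepest-ascent paths, Box-Behnken designs
    with quadratic-term aliasing diagnostics, partial-sum-of-squares ANOVA,
    box-constrained quadratic response-surface optimization, surfactant
    activity tests, and segmented-regression estimation of the critical
    micelle concentration. Includes synthetic-data generators so every stage
    can be validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
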