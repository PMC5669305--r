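Package: coalcough
Title: Difference-in-Differences Analysis of Coal Plant Exposure and
    Respiratory Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the health externalities of new coal-fired
    power plants from two-wave household panel surveys. Implements the
    fixed-effects linear-probability difference-in-differences estimator with
    cluster-robust (CR1) sandwich variance, district-level randomization
    inference, the two-period conditional fixed-effects logit, baseline
    balance and pre-trend diagnostics (including a principal-component
    pre-trend outcome), falsification and migration-exclusion checks, a
    capacity dose-response analysis, and a discounted cost-of-illness
    calculator. Includes a seeded synthetic panel generator emulating the
    two-stage (district / primary sampling unit / household) survey structure
    so the full pipeline is testable without confidential microdata.
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
    survival,
    sandwich,
    withr,
    jsonlite
Config/testthat/edition: 3
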