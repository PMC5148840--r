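Package: isiequiv
Title: OGTT Insulin Sensitivity Indices and Ethnic-Specific Anthropometric
    Equivalence Cut-Offs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes oral glucose tolerance test (OGTT) derived indices of
    insulin sensitivity and beta-cell function (Matsuda insulin sensitivity
    index, corrected insulin response, oral disposition index), classifies
    insulin resistance against a reference population's ISI tertiles, and
    derives group-specific body mass index and waist circumference cut-offs
    at which a comparison population has the same age-adjusted insulin
    sensitivity as the reference population at standard obesity thresholds.
    Includes standardized-beta multivariate regression with gated interaction
    scanning and variance-inflation screening, age-adjusted group comparisons
    of means and proportions, a calibrated synthetic two-group OGTT cohort
    generator for end-to-end testing, and CSV/JSON input-output with a thin
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    car
Config/testthat/edition: 3
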