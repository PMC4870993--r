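Package: gistage
Title: Glaucoma Severity Index Staging and Surgical Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stages glaucoma patients with a composite severity index built
    from baseline intraocular pressure, medication burden, and visual-field
    damage, and analyses surgical outcomes by severity group: longitudinal
    pressure and medication reduction, a univariate-screen-then-multivariate
    regression of one-year pressure reduction on clinical covariates, and
    Kaplan-Meier survival with a two-consecutive-visit failure rule and
    log-rank comparison. Includes a calibrated synthetic cohort generator so
    the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
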