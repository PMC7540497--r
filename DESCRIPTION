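Package: enwasr
Title: Environment-Wide Association Scans for Epidemiological Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for environment-wide association studies (EnWAS) of
    mixed-type exposure data against a continuous trait outcome.
    Implements dictionary-driven variable harmonization (conditional-question
    merging, "do not know" recoding, category collapsing), dataset-level
    quality-control filters, scoring of the 18-item Social Responsiveness
    Scale outcome with a square-root transformation, mass-univariate
    covariate-adjusted linear regression over a discovery/test split with
    two-stage false-discovery-rate control, chained-equation covariate
    imputation, sensitivity analyses, a synthetic cohort generator with
    block-correlated mixed-type exposures, simulation-based estimation of
    family-wise error rates for the two-stage design, and reporting
    (Manhattan plots, correlation heatmaps, nonresponse comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
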