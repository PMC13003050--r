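Package: no2risk
Title: Occupational Risk Assessment of Traffic-Related Indoor Nitrogen Dioxide
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for assessing occupational exposure risk from
    traffic-related nitrogen dioxide (NO2) measured inside hospitals.
    Implements a 3x3 likelihood-by-severity risk matrix with configurable
    concentration and occupancy bands, a measurement data model with
    sampling quality control, a moment-calibrated truncated-normal
    generator for synthetic measurement campaigns, deterministic risk-table
    fixtures, a statistical battery (normality, one-way ANOVA with Fisher
    LSD post-hoc, two-sample t-tests including from summary statistics,
    Spearman rank correlation), and an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
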