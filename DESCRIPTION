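Package: ki67agree
Title: Inter- and Intra-Observer Reliability Analysis for Ki-67 Scoring Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing multi-rater, multi-replicate
    agreement studies of the Ki-67 labelling index in breast cancer pathology.
    Implements simultaneous inter- and intra-observer reliability coefficients
    from a balanced two-way crossed random-effects ANOVA with replicates,
    one-sided confidence bounds and tests against a reliability threshold,
    Fleiss' kappa at clinical cut-offs with bias-corrected bootstrap inference,
    weighted-sum ranking of assessment methods, Bland-Altman agreement
    summaries, power and sample-size calculations for reliability designs, and
    a crossed random-effects generator for synthetic rating tables.
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
    withr
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
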