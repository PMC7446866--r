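Package: homeclass
Title: Classification of Homelessness from Linked Administrative Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying homelessness in linked person-level
    administrative data and for estimating its association with fatal
    opioid overdose. Implements a four-criterion composite case
    definition (diagnosis codes on insurance and hospital claims,
    monthly housing-status records from the state mental-health system,
    ambulance narrative keywords, and prescription addresses matching
    emergency shelters), ICD-10 classification of fatal opioid-related
    overdoses from death records, a stratified-split and downsampled
    logistic classification workflow with confusion-matrix and
    rank-based AUC evaluation, and probabilistic risk-score weighting
    of group sizes and death counts to compare overdose rates with
    log-normal confidence intervals. A seeded synthetic-data generator
    emulates the statistical structure of such a linked warehouse so
    the full pipeline is testable without access to restricted records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
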