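Package: faersignal
Title: Disproportionality Signal Detection and Time-to-Onset Modelling for
    FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for safety signal detection in the FDA
    Adverse Event Reporting System (FAERS). Parses the quarterly
    dollar-delimited ASCII tables, applies the FDA-recommended case
    deduplication (latest FDA_DT, ties broken by higher PRIMARYID), selects
    drug cohorts by suspect role, and mines drug-event associations with the
    reporting odds ratio (Wald confidence intervals) and the Bayesian
    confidence propagation neural network information component (IC, IC025).
    Includes sex/age subgroup and death-outcome stratified analyses,
    high-level-group-term screening for secondary malignancies, Weibull
    time-to-onset modelling with failure-type classification, and a
    synthetic FAERS-like report generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
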