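Package: auxofate
Title: Single-Cell Growth and Amino Acid Leakage Analysis for
    Auxotroph-Wildtype Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for the fate of amino-acid auxotrophic
    mutants in spatially structured wildtype populations imaged in
    microfluidic growth chambers. Provides a validated track-table
    interchange format, a synthetic chamber generator emulating
    time-lapse tracking data, single-cell specific growth-rate
    estimation by log-linear regression with quality filters, local
    neighborhood composition statistics with permutation nulls, a
    Monod-type amino-acid leakage/uptake growth model with critical
    leakage thresholds, and inference of wildtype leakage rates from
    observed auxotroph growth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
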