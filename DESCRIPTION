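Package: tadshift
Title: Identification of Structurally Reorganized Topologically
    Associating Domains from Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical detection of topologically associating domains
    (TADs) whose internal Hi-C contact structure is reorganized between
    two biological conditions. For each TAD the log-ratio of the two
    balanced contact matrices is standardized within each off-diagonal
    (genomic distance stratum) and the largest eigenvalue of the
    resulting matrix is tested against the Tracy-Widom beta = 1 law,
    giving a one-sided P value per TAD with Benjamini-Hochberg control
    across TADs. Significant TADs are classified into six reorganization
    subtypes (strength-change, loss, split, merge, zoom, complex) from
    interval relations between the two conditions' TAD lists. Additional
    tools cover missing-value imputation, single-cell Hi-C pseudo-bulk
    aggregation, reproducibility curves, cell-to-population and
    cell-to-cell variability analyses, and seeded synthetic-data
    generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
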