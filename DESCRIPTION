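Package: guidesignal
Title: High-Precision Retrieval of Signal Publications for Clinical Guideline Updates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes heterogeneous sources of clinical evidence (trial
    reports, registered trials, curated precision-oncology assertions and
    machine-readable guidelines) onto a shared concept hierarchy, and
    retrieves candidate "signal publications" for guideline updates via a
    precision-oriented conjunctive filter cascade contextualized by current
    guideline content. Includes screening-log based evaluation with an
    unknown-relevance aware confusion accounting, research-translation
    time-lag analysis across guideline versions, and a deterministic
    synthetic-data generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
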