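Package: recurrex
Title: Identify Breast Cancer Local Recurrence from Clinical Progress Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A concept-based phenotyping pipeline that identifies breast
    cancer local recurrence from free-text progress notes and pathology
    report counts. Notes are split into sentences and normalized, mapped to
    UMLS concept identifiers with a dictionary tagger, filtered by NegEx
    negation scoping and sentence-level negation/uncertainty cues, and gated
    by a curated positive concept set. Within-sentence power sets of the
    retained concepts (sizes one to three) plus the count of pathology
    reports filed at least 120 days after primary diagnosis form the feature
    space for a chi-square-selected support vector machine. A synthetic
    corpus generator with template sentences and class-conditional pathology
    report counts makes every stage testable without protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    yaml,
    Matrix,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
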