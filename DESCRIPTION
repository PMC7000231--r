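Package: fhhscreen
Title: Family-Health-History Screening for Hereditary Cancer Genetic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Population-screening clinical decision support for hereditary
    breast/ovarian and colorectal cancer. Reads family-health-history (FHH)
    data from FHIR-style JSON (Patient, Encounter, FamilyMemberHistory),
    maps local relationship and diagnosis terms to normalized pedigree
    concepts, extracts fuzzy ages of onset and lineage sides from short
    free-text comments, evaluates NCCN-derived eligibility criteria with a
    criteria-agnostic rule engine, and manages the resulting registry
    through an outreach state machine with disposition reporting. Includes
    a synthetic-cohort generator with planted ground truth so the whole
    pipeline is testable without any EHR connection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
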