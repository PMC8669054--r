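Package: cohortforge
Title: Cohort Assembly, Accession Resolution and Attrition Accounting for
    Large CT Imaging Datasets
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for curating large abdominal-CT cohorts from radiology
    research-registry exports and hospital PACS study indices: registry
    filtering and earliest-exam selection, exam-description keyword
    exclusion, per-site medical record number (MRN) and accession (ACC)
    normalization, de-novo accession resolution against PACS indices via a
    body-part and date-window cascade, content-level triage of retrieved
    DICOM studies into non-recoverable failure categories, stage-by-stage
    attrition accounting, and a producer-consumer capacity model for bulk
    exam transfer. Ships a deterministic synthetic RIS/PACS fixture
    generator that injects the documented real-world failure modes
    (dropped leading zeros, legacy accession prefixes, billing-only
    accessions, pelvis/chest image linkage, date offsets, topogram-only,
    corrupted, missing and mis-encoded studies) with ground-truth labels,
    including a replica preset at the scale of a published multi-hospital
    retrieval effort.
License: MIT
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
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
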