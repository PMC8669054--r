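# The replica fixture run is expensive enough to share: generate, render
# and run the pipeline once per test session.
.replica_cache <- new.env(parent = emptyenv())

replica_run <- function() {
  if (is.null(.replica_cache$run)) {
    dicom_dir <- file.path(tempdir(), "cohortforge-replica-dicom")
    .replica_cache$run <- run_replica(paper_replica_config(),
                                      dicom_dir = dicom_dir)
  }
  .replica_cache$run
}

# A small fully-loaded configuration exercising every injection mode.
small_config <- function(seed = 42L) {
  fixture_config(
    seed = seed, n_patients = 150L, n_extra_exams = 40L,
    injections = list(
      mislabeled_interventional = 6L, mrn_zero_dropped = 15L,
      acc_prefix_added = 10L, billing_only_acc = 5L, linkage_pelvis = 4L,
      linkage_chest = 3L, date_offset = 8L, mrn_acc_discrepancy = 3L,
      topogram_only = 2L, missing = 2L, corrupted = 2L, test_patient = 1L,
      encoding_error = 2L, adversarial_misresolution = 2L),
    decoys = list(inpatient = 4L, wrong_year = 4L, age_low = 2L,
                  age_high = 2L, excluded_group = 4L, non_ct = 2L,
                  no_abd = 2L),
    n_clean_rendered = 3L)
}
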