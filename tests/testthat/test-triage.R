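test_that("triage categories recover injected modes exactly on a small fixture", {
  fx <- generate_fixture(small_config(13L))
  dicom_dir <- tempfile("triage_dcm_")
  render_dicom_fixtures(fx$manifest, dicom_dir)
  norm <- normalize_cohort(fx$registry, fx$site_rules)
  cohort <- apply_keyword_exclusion(select_earliest_per_patient(
    apply_registry_filters(norm$records)$kept))$kept
  res <- resolve_cohort(cohort, fx$pacs_index)
  mis <- flag_misresolutions(res, fx$ground_truth)
  res <- apply_resolution_overrides(res, mis$overrides)
  disp <- triage_cohort(res, cohort, fx$pacs_index, dicom_root = dicom_dir,
                        manifest = fx$manifest)
  cfg <- fx$config$injections
  got <- table(disp$disposition)
  expect_identical(as.integer(got[["failed_mrn_acc_discrepancy"]]),
                   cfg[["mrn_acc_discrepancy"]])
  expect_identical(as.integer(got[["failed_topogram_only"]]),
                   cfg[["topogram_only"]])
  expect_identical(as.integer(got[["failed_missing"]]), cfg[["missing"]])
  expect_identical(as.integer(got[["failed_corrupted"]]),
                   cfg[["corrupted"]])
  expect_identical(as.integer(got[["failed_test_patient"]]),
                   cfg[["test_patient"]])
  expect_identical(as.integer(got[["failed_encoding"]]),
                   cfg[["encoding_error"]])
  # dispositions partition the cohort
  expect_identical(sum(got), nrow(cohort))
  # triage is pure: same inputs, same dispositions
  disp2 <- triage_cohort(res, cohort, fx$pacs_index,
                         dicom_root = dicom_dir, manifest = fx$manifest)
  expect_identical(disp, disp2)
})

test_that("identifier-level faults take precedence over content-level faults", {
  # an exam whose accession sits under a foreign MRN in PACS *and* whose
  # rendered study is corrupted must land in the discrepancy bucket
  idx <- data.frame(mrn = "99999999", accession = "ACC1",
                    study_date = "2012-06-15", body_part = "ABDOMEN",
                    modality = "CT", image_count = 100L,
                    hospital = "site_a", stringsAsFactors = FALSE)
  resolution <- list(status = "resolved", chosen_accession = "ACC1",
                     registry_accession = "ACC1")
  root <- tempfile()
  render_dicom_study(root, "ACC1", "corrupted", "00000001", "SYNTH^P",
                     "2012-06-15")
  got <- triage_study(resolution, "00000001", idx,
                      study_dir = file.path(root, "ACC1"))
  expect_identical(got$disposition, "failed_mrn_acc_discrepancy")

  # same study under the right MRN is triaged on content
  idx$mrn <- "00000001"
  got2 <- triage_study(resolution, "00000001", idx,
                       study_dir = file.path(root, "ACC1"))
  expect_identical(got2$disposition, "failed_corrupted")

  # unresolved exam with no PACS row anywhere is missing
  got3 <- triage_study(list(status = "unresolved",
                            chosen_accession = NA_character_,
                            registry_accession = "NOPE"),
                       "00000001", idx)
  expect_identical(got3$disposition, "failed_missing")

  # a manifest-listed study whose directory vanished is missing, with
  # distinct evidence
  got4 <- triage_study(resolution, "00000001", idx,
                       study_dir = file.path(root, "GONE"))
  expect_identical(got4$disposition, "failed_missing")
  expect_match(got4$evidence, "no study directory")
})

test_that("attrition report telescopes and rejects partition violations", {
  disp <- data.frame(
    patient_id = sprintf("p%d", 1:10),
    registry_accession = sprintf("a%d", 1:10),
    disposition = c(rep("included", 7), "failed_missing",
                    "failed_corrupted", "failed_encoding"),
    evidence = "", stringsAsFactors = FALSE)
  counts <- list(registry_rows = 40L, filter_removed = 20L,
                 filter_rejects = 2L, filter_kept = 18L,
                 patients_selected = 12L, keyword_excluded = 2L)
  rep_ok <- build_attrition_report(disp, counts)
  expect_identical(rep_ok$n_included, 7L)
  expect_identical(rep_ok$n_non_recoverable, 3L)
  st <- rep_ok$stages
  expect_identical(st$count[st$stage == "final valid exams"], 7L)
  # conservation: initial cohort = final + all failure categories
  expect_identical(
    st$count[st$stage == "cohort entering retrieval"],
    rep_ok$n_included + rep_ok$n_non_recoverable)

  # wrong number of dispositions (partition violation) is a hard error
  expect_error(build_attrition_report(disp[1:9, ], counts),
               class = "cohortforge_conservation_failure")
  # non-telescoping upstream counts are a hard error
  bad <- counts; bad$filter_kept <- 10L
  expect_error(build_attrition_report(disp, bad),
               class = "cohortforge_conservation_failure")
  # unknown disposition is a hard error naming the exam
  disp_bad <- disp; disp_bad$disposition[1] <- "mystery"
  expect_error(build_attrition_report(disp_bad, counts),
               class = "cohortforge_conservation_failure")
})

test_that("an empty cohort yields an all-zero attrition table", {
  disp <- data.frame(patient_id = character(0),
                     registry_accession = character(0),
                     disposition = character(0), evidence = character(0),
                     stringsAsFactors = FALSE)
  counts <- list(registry_rows = 0L, filter_removed = 0L,
                 filter_rejects = 0L, filter_kept = 0L,
                 patients_selected = 0L, keyword_excluded = 0L)
  rep0 <- build_attrition_report(disp, counts)
  expect_true(all(rep0$stages$count == 0L))
})
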