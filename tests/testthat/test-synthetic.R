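test_that("identical configs generate byte-identical fixtures", {
  cfg <- small_config(99L)
  a <- generate_fixture(cfg)
  b <- generate_fixture(cfg)
  expect_identical(a$registry, b$registry)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$pacs_index, b$pacs_index)
  expect_identical(a$manifest, b$manifest)
  # and the serialized form is byte-identical too
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture(a, d1); write_fixture(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("injected-mode counts in the ground truth equal the config exactly", {
  cfg <- small_config(3L)
  fx <- generate_fixture(cfg)
  got <- table(fx$ground_truth$injected_mode)
  for (m in names(cfg$injections)) {
    n_got <- if (m %in% names(got)) as.integer(got[[m]]) else 0L
    expect_identical(n_got, cfg$injections[[m]], label = m)
  }
})

test_that("a zero-injection, zero-decoy config yields a clean registry", {
  cfg <- fixture_config(seed = 5L, n_patients = 30L, n_extra_exams = 5L)
  fx <- generate_fixture(cfg)
  expect_true(all(fx$ground_truth$injected_mode == "none"))
  expect_identical(nrow(fx$registry), 35L)
  filt <- apply_registry_filters(fx$registry)
  expect_identical(nrow(filt$kept), 35L)
  norm <- normalize_cohort(fx$registry, fx$site_rules)
  expect_identical(norm$n_reformatted, 0L)
})

test_that("invalid configurations are rejected with named errors", {
  expect_error(fixture_config(n_patients = 10L,
                              injections = list(missing = 11L)),
               class = "cohortforge_injection_overflow")
  expect_error(fixture_config(injections = list(zebra = 1L)),
               class = "cohortforge_bad_fixture_config")
  expect_error(fixture_config(date_offset_max = 5L),
               class = "cohortforge_bad_fixture_config")
  expect_error(fixture_config(n_patients = -1L),
               class = "cohortforge_bad_fixture_config")
  # dangling exam key
  cfg <- fixture_config(seed = 5L, n_patients = 10L, n_extra_exams = 0L)
  reg <- generate_registry(cfg)
  gt_bad <- rbind(reg$ground_truth,
                  data.table::data.table(
                    patient_id = "99999999", registry_accession = "X",
                    injected_mode = "none", true_accession = "X",
                    offset_days = NA_integer_, mrn_canonical = "99999999",
                    hospital = "site_a", exam_date = "2012-01-01"))
  expect_error(generate_pacs_index(reg$registry, gt_bad, cfg),
               class = "cohortforge_dangling_exam_key")
})

test_that("every recoverable exam resolves to its true accession", {
  fx <- generate_fixture(small_config(21L))
  norm <- normalize_cohort(fx$registry, fx$site_rules)
  cohort <- apply_keyword_exclusion(select_earliest_per_patient(
    apply_registry_filters(norm$records)$kept))$kept
  res <- resolve_cohort(cohort, fx$pacs_index)
  gt <- data.table::as.data.table(fx$ground_truth)
  merged <- merge(res, gt[, c("patient_id", "registry_accession",
                              "injected_mode", "true_accession")],
                  by = c("patient_id", "registry_accession"))
  recoverable <- merged[!merged$injected_mode %in%
                          c("mrn_acc_discrepancy", "topogram_only",
                            "missing", "corrupted", "test_patient",
                            "encoding_error", "adversarial_misresolution",
                            "mislabeled_interventional"), ]
  expect_true(all(recoverable$status == "resolved"))
  expect_identical(sum(recoverable$chosen_accession !=
                         recoverable$true_accession), 0L)
  # and every adversarial exam mis-resolves, by construction
  adv <- merged[merged$injected_mode == "adversarial_misresolution", ]
  expect_true(all(adv$status == "resolved"))
  expect_true(all(adv$chosen_accession != adv$true_accession))
})

test_that("PACS rows honour the linkage modes", {
  fx <- generate_fixture(small_config(8L))
  gt <- fx$ground_truth
  idx <- fx$pacs_index
  pelv <- gt[gt$injected_mode == "linkage_pelvis", ]
  for (i in seq_len(nrow(pelv))) {
    true_row <- idx[idx$accession == pelv$true_accession[i], ]
    expect_identical(normalize_body_part(true_row$body_part), "pelvis")
    expect_gt(true_row$image_count, 20L)
    reg_row <- idx[idx$accession == pelv$registry_accession[i], ]
    expect_lte(reg_row$image_count, 20L)
  }
  miss <- gt[gt$injected_mode == "missing", ]
  expect_identical(nrow(idx[idx$accession %in% miss$registry_accession, ]),
                   0L)
  clean <- gt[gt$injected_mode == "none" &
                !is.na(gt$true_accession), ][1, ]
  row <- idx[idx$accession == clean$registry_accession, ]
  expect_identical(nrow(row), 1L)
  expect_identical(normalize_body_part(row$body_part) %in%
                     c("abdomen", "gi", "gu", "body"), TRUE)
  expect_gt(row$image_count, 20L)
})
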