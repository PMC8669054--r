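make_row <- function(patient_id = "10000001", accession = "5000000001",
                     hospital = "site_b", exam_date = "2012-06-01",
                     exam_time = "08:00:00",
                     exam_description = "CT ABD/PELVIS W CONTRAST",
                     exam_group = "abdomen", modality = "CT",
                     patient_type = "outpatient", age = 50L,
                     exam_code = "CTAB01") {
  data.frame(patient_id = patient_id, accession = accession,
             hospital = hospital, exam_date = exam_date,
             exam_time = exam_time, exam_description = exam_description,
             exam_group = exam_group, modality = modality,
             patient_type = patient_type, age = age, exam_code = exam_code,
             stringsAsFactors = FALSE)
}

test_that("registry filters agree with a row-by-row predicate oracle", {
  cfg <- cohort_filter_config()
  rows <- rbind(
    make_row(),                                         # clean
    make_row(modality = "MR"),                          # wrong modality
    make_row(exam_date = "2011-06-01"),                 # wrong year
    make_row(exam_description = "CT CHEST W CONTRAST"), # no "Abd"
    make_row(exam_group = "hdnk"),                      # excluded group
    make_row(patient_type = "inpatient"),               # excluded type
    make_row(age = 17L),                                # under age
    make_row(age = 100L),                               # over age
    make_row(age = 18L),                                # inclusive low bound
    make_row(age = 99L))                                # inclusive high bound
  out <- apply_registry_filters(rows, cfg)
  oracle <- vapply(seq_len(nrow(rows)),
                   function(i) oracle_keep(rows[i, ], cfg), logical(1))
  expect_identical(nrow(out$kept), sum(oracle))
  expect_setequal(out$kept$age, rows$age[oracle])
  # partition: every row lands in exactly one bucket
  expect_identical(nrow(out$kept) + nrow(out$removed) + nrow(out$rejects),
                   nrow(rows))
  # inclusive age bounds kept
  expect_true(all(c(18L, 99L) %in% out$kept$age))
})

test_that("malformed rows are quarantined with reasons, not dropped", {
  rows <- rbind(make_row(), make_row(exam_date = "not-a-date"),
                make_row(age = "??"))
  out <- apply_registry_filters(rows)
  expect_identical(nrow(out$rejects), 2L)
  expect_setequal(out$rejects$reason,
                  c("unparseable exam_date", "unparseable age"))
  expect_identical(nrow(out$kept) + nrow(out$removed) + nrow(out$rejects),
                   nrow(rows))
})

test_that("filtering is idempotent and empty input yields empty output", {
  rows <- rbind(make_row(), make_row(patient_type = "inpatient"))
  once <- apply_registry_filters(rows)$kept
  twice <- apply_registry_filters(once)$kept
  expect_identical(as.data.frame(twice), as.data.frame(once))
  empty <- apply_registry_filters(make_row()[0, ])
  expect_identical(nrow(empty$kept), 0L)
})

test_that("earliest-exam selection is order-invariant and breaks ties by time then accession", {
  rows <- rbind(
    make_row(patient_id = "p1", accession = "B", exam_date = "2012-03-01"),
    make_row(patient_id = "p1", accession = "A", exam_date = "2012-01-05"),
    # p2: same date, times differ
    make_row(patient_id = "p2", accession = "C", exam_date = "2012-02-01",
             exam_time = "14:00:00"),
    make_row(patient_id = "p2", accession = "D", exam_date = "2012-02-01",
             exam_time = "09:30:00"),
    # p3: same date, one missing time (recorded time wins)
    make_row(patient_id = "p3", accession = "E", exam_date = "2012-02-01",
             exam_time = ""),
    make_row(patient_id = "p3", accession = "F", exam_date = "2012-02-01",
             exam_time = "23:59:00"),
    # p4: same date and time, lexicographic accession
    make_row(patient_id = "p4", accession = "H", exam_date = "2012-05-01"),
    make_row(patient_id = "p4", accession = "G", exam_date = "2012-05-01"))
  expected <- c(p1 = "A", p2 = "D", p3 = "F", p4 = "G")
  # permutation oracle: every input ordering yields the same choice
  set.seed(5)
  perms <- c(list(seq_len(nrow(rows))),
             replicate(20, sample.int(nrow(rows)), simplify = FALSE))
  for (p in perms) {
    sel <- select_earliest_per_patient(rows[p, ])
    got <- setNames(sel$accession, sel$patient_id)
    expect_identical(got[names(expected)], expected)
  }
  expect_identical(nrow(select_earliest_per_patient(rows)),
                   length(unique(rows$patient_id)))
})

test_that("keyword exclusion is a case-insensitive substring partition", {
  kws <- cohort_filter_config()$exclusion_keywords
  rows <- rbind(
    make_row(accession = "1",
             exam_description = "CT Abd/Pelvis with contrast"),
    make_row(accession = "2", exam_description = "CT Abd Biopsy guidance"),
    make_row(accession = "3", exam_description = "CT abd PERC drain chk"),
    make_row(accession = "4", exam_description = "CT ABD DRG CHECK"),
    make_row(accession = "5", exam_description = "CT Abdomen routine"))
  out <- apply_keyword_exclusion(rows, kws)
  # reference lowercase-substring scan
  oracle_hit <- vapply(rows$exam_description, function(d) {
    any(vapply(kws, function(k) grepl(k, tolower(d), fixed = TRUE),
               logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  expect_setequal(out$excluded$accession, rows$accession[oracle_hit])
  expect_setequal(out$kept$accession, rows$accession[!oracle_hit])
  expect_identical(nrow(out$kept) + nrow(out$excluded), nrow(rows))
  expect_true("1" %in% out$kept$accession)
  expect_true(all(c("2", "3") %in% out$excluded$accession))
})
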