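mk_index <- function(acc, diff, bp, count, mrn = "00000001",
                     base = as.Date("2012-06-15")) {
  data.frame(mrn = mrn, accession = acc,
             study_date = as.character(base + diff), body_part = bp,
             modality = "CT", image_count = count,
             hospital = "site_a", stringsAsFactors = FALSE)
}

test_that("candidate search enforces the strict >20 image floor and the date window", {
  idx <- rbind(mk_index("A20", 0, "ABDOMEN", 20L),
               mk_index("A21", 0, "ABDOMEN", 21L))
  got <- find_candidates(idx, "00000001", "2012-06-15", 0L)
  expect_identical(got$accession, "A21")

  # 7-study hand case, window 0 vs window 4 against a linear scan
  diffs <- c(-5L, -4L, -2L, 0L, 1L, 4L, 6L)
  idx7 <- mk_index(sprintf("S%d", 1:7), diffs, "ABDOMEN", 50L)
  w0 <- find_candidates(idx7, "00000001", "2012-06-15", 0L)
  w4 <- find_candidates(idx7, "00000001", "2012-06-15", 4L)
  expect_setequal(w0$accession, idx7$accession[abs(diffs) <= 0])
  expect_setequal(w4$accession, idx7$accession[abs(diffs) <= 4])
  # empty index is a valid empty result
  expect_identical(nrow(find_candidates(idx7[0, ], "00000001",
                                        "2012-06-15", 4L)), 0L)
})

test_that("cascade prefers same-date abdomen, then pelvis/chest, then the expanded window", {
  base <- "2012-06-15"
  idx <- rbind(mk_index("ABD", 0, "ABDOMEN", 30L),
               mk_index("PEL", 0, "PELVIS", 300L))
  r <- resolve_accession(find_candidates(idx, "00000001", base, 0L),
                         find_candidates(idx, "00000001", base, 4L))
  expect_identical(r$chosen_accession, "ABD")
  expect_identical(r$tier, "abdomen_same_window")

  # a same-date pelvis beats a nearer-tier-name abdomen 3 days away
  idx2 <- rbind(mk_index("PEL0", 0, "PELVIS", 30L),
                mk_index("ABD3", 3, "ABDOMEN", 300L))
  r2 <- resolve_accession(find_candidates(idx2, "00000001", base, 0L),
                          find_candidates(idx2, "00000001", base, 4L))
  expect_identical(r2$chosen_accession, "PEL0")
  expect_identical(r2$tier, "pelvis_or_chest_same_window")

  # nothing at all -> unresolved
  r3 <- resolve_accession(mk_index("X", 0, "ABDOMEN", 50L)[0, ],
                          mk_index("X", 0, "ABDOMEN", 50L)[0, ])
  expect_identical(r3$status, "unresolved")
  expect_true(is.na(r3$chosen_accession))
})

test_that("resolver equals the brute-force cascade oracle on small candidate sets", {
  run_both <- function(cand) {
    w0 <- cand[cand$abs_diff == 0, , drop = FALSE]
    got <- resolve_accession(w0, cand)
    want <- oracle_resolve(cand)
    if (is.na(want)) expect_identical(got$status, "unresolved")
    else expect_identical(got$chosen_accession, want)
  }
  set.seed(97)
  # exhaustive over sets of size 1 and 2 drawn from a reduced universe
  uni <- expand.grid(body_part = c("ABDOMEN", "PELVIS", "CHEST"),
                     diff = c(0L, 1L, -3L, 4L),
                     image_count = c(21L, 50L), stringsAsFactors = FALSE)
  mk <- function(i, acc) mk_index(acc, uni$diff[i], uni$body_part[i],
                                  uni$image_count[i])[, c(
    "mrn", "accession", "study_date", "body_part", "modality",
    "image_count")]
  n <- nrow(uni)
  for (i in seq_len(n)) {
    c1 <- mk(i, "ACC1"); c1$abs_diff <- abs(uni$diff[i])
    run_both(c1)
    for (j in seq_len(n)) {
      if (j <= i) next
      c2 <- rbind(c1, {
        x <- mk(j, "ACC2"); x$abs_diff <- abs(uni$diff[j]); x
      })
      run_both(c2)
    }
  }
  # seeded random sample of larger sets from the full universe
  for (rep in 1:400) {
    run_both(random_candidates(sample(3:6, 1)))
  }
})

test_that("resolution is invariant to candidate order and window enlargement never flips a same-date tier", {
  set.seed(31)
  for (rep in 1:100) {
    cand <- random_candidates(sample(2:6, 1))
    w0 <- cand[cand$abs_diff == 0, , drop = FALSE]
    ref <- resolve_accession(w0, cand)
    for (k in 1:5) {
      p <- sample.int(nrow(cand))
      got <- resolve_accession(w0[sample.int(nrow(w0)), , drop = FALSE],
                               cand[p, , drop = FALSE])
      expect_identical(got$chosen_accession, ref$chosen_accession)
      expect_identical(got$tier, ref$tier)
    }
    # monotonicity: if the exam resolves among same-date candidates alone,
    # adding the expanded-window candidates changes nothing
    same_only <- resolve_accession(w0, w0)
    if (same_only$status == "resolved") {
      expect_identical(ref$chosen_accession, same_only$chosen_accession)
      expect_identical(ref$tier, same_only$tier)
    }
  }
})

test_that("vectorized cohort resolution matches per-exam resolution", {
  fx <- generate_fixture(small_config(7L))
  norm <- normalize_cohort(fx$registry, fx$site_rules)
  filt <- apply_registry_filters(norm$records)
  cohort <- apply_keyword_exclusion(
    select_earliest_per_patient(filt$kept))$kept
  res <- resolve_cohort(cohort, fx$pacs_index)
  set.seed(12)
  for (i in sample.int(nrow(cohort), 30)) {
    row <- cohort[i, ]
    w0 <- find_candidates(fx$pacs_index, row$mrn_canonical, row$exam_date,
                          0L)
    w4 <- find_candidates(fx$pacs_index, row$mrn_canonical, row$exam_date,
                          4L)
    single <- resolve_accession(w0, w4)
    got <- res[res$patient_id == row$patient_id &
                 res$registry_accession == row$accession_canonical, ]
    expect_identical(got$status, single$status)
    if (single$status == "resolved") {
      expect_identical(got$chosen_accession, single$chosen_accession)
      expect_identical(got$tier, single$tier)
    }
  }
})

test_that("discrepancy and mis-resolution flags count planted cases exactly", {
  res <- data.frame(
    patient_id = sprintf("p%d", 1:5),
    registry_accession = c("1", "2", "3", "4", "5"),
    status = c("resolved", "resolved", "resolved", "resolved",
               "unresolved"),
    chosen_accession = c("1", "9", "3", "8", NA),
    stringsAsFactors = FALSE)
  disc <- flag_registry_discrepancies(res)
  expect_identical(disc$n, 2L)
  expect_identical(disc$flagged$registry_accession, c("2", "4"))

  gt <- data.frame(patient_id = sprintf("p%d", 1:5),
                   registry_accession = c("1", "2", "3", "4", "5"),
                   true_accession = c("1", "9", "7", "8", "5"),
                   stringsAsFactors = FALSE)
  mis <- flag_misresolutions(res, gt)
  expect_identical(mis$n, 1L)
  expect_identical(mis$overrides$registry_accession, "3")
  fixed <- apply_resolution_overrides(res, mis$overrides)
  expect_identical(
    fixed$chosen_accession[fixed$registry_accession == "3"], "7")
  expect_error(flag_misresolutions(res, NULL),
               class = "cohortforge_missing_ground_truth")
})
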