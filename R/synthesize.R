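# Synthetic RIS/PACS fixture generation. The generator emits a registry
# export, per-hospital PACS study indices, a ground-truth label table and a
# DICOM retrieval manifest, with every documented real-world failure mode
# injected at configurable counts and recorded per exam, so the curation
# pipeline can be scored exactly.

INJECTION_MODES <- c("mislabeled_interventional", "mrn_zero_dropped",
                     "acc_prefix_added", "billing_only_acc",
                     "linkage_pelvis", "linkage_chest", "date_offset",
                     "mrn_acc_discrepancy", "topogram_only", "missing",
                     "corrupted", "test_patient", "encoding_error",
                     "adversarial_misresolution")

DECOY_KINDS <- c("inpatient", "wrong_year", "age_low", "age_high",
                 "excluded_group", "non_ct", "no_abd")

NON_RECOVERABLE_MODES <- c("mrn_acc_discrepancy", "topogram_only",
                           "missing", "corrupted", "test_patient",
                           "encoding_error")

CONTENT_FAILURE_MODES <- c("topogram_only", "corrupted", "test_patient",
                           "encoding_error")

.clean_descriptions <- c(
  "CT ABD/PELVIS W CONTRAST", "CT ABDOMEN WO CONTRAST",
  "CT ABD/PELVIS WO CONTRAST", "CT ABD W/WO CONTRAST",
  "CT ABD/PEL/CHEST W CONTRAST", "CT ABDOMEN MULTIPHASE")

.mislabeled_descriptions <- c(
  "CT ABD BIOPSY GUIDANCE", "CT ABD PERC DRAINAGE", "CT ABD RF ABLATION",
  "CT GUIDANCE FNA ABD", "CT ABD DRG CHECK", "CT INTERV ABD EMBOLIZATION",
  "CT BONE SURVEY ABD")

.abd_spellings <- c("ABDOMEN", "Abdomen", "ABD", "GI", "GU", "BODY")
.pelvis_spellings <- c("PELVIS", "Pelvis")
.chest_spellings <- c("CHEST", "Thorax")

#' Configure a synthetic RIS/PACS fixture
#'
#' Fixes everything the generator needs: the cohort size, the number of
#' additional (later) exams per-patient history contributes, per-mode
#' injection counts for each documented failure mode, decoy rows that the
#' upstream registry filters must remove, and the hospital roster with the
#' identifier conventions of the one site whose export corrupts MRNs and
#' accessions.
#'
#' Injection modes: `mislabeled_interventional` (keyword-excludable
#' description), `mrn_zero_dropped` and `acc_prefix_added` (identifier
#' reformatting at the corrupting site), `billing_only_acc`,
#' `linkage_pelvis`, `linkage_chest` (the image-bearing accession differs
#' from the registry accession), `date_offset` (PACS study date off by up
#' to `date_offset_max` days), `mrn_acc_discrepancy`, `topogram_only`,
#' `missing`, `corrupted`, `test_patient`, `encoding_error` (the six
#' non-recoverable categories), and `adversarial_misresolution` (a decoy
#' study constructed so the resolution cascade provably picks the wrong
#' accession).
#'
#' @param seed integer RNG seed; identical configs generate byte-identical
#'   fixtures.
#' @param n_patients number of patients whose earliest exam survives the
#'   registry filters.
#' @param n_extra_exams additional later exams spread over the patients
#'   (so filtered rows = `n_patients + n_extra_exams`).
#' @param injections named list/vector of per-mode counts (missing modes
#'   default to 0).
#' @param decoys named list/vector of per-kind decoy row counts (each
#'   decoy fails exactly one upstream filter).
#' @param hospitals site codes; the first is the identifier-corrupting
#'   site.
#' @param mrn_pad_width,acc_strip_prefix identifier rules of the
#'   corrupting site.
#' @param date_offset_max largest |study date - exam date| injected, in
#'   days (at most 4, the resolver's expanded window).
#' @param n_clean_rendered clean studies rendered to DICOM alongside every
#'   injected-failure study.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           n_patients = 100L,
                           n_extra_exams = 20L,
                           injections = list(),
                           decoys = list(),
                           hospitals = c("site_a", "site_b"),
                           mrn_pad_width = 8L,
                           acc_strip_prefix = "A",
                           date_offset_max = 4L,
                           n_clean_rendered = 10L) {
  inj <- stats::setNames(rep(0L, length(INJECTION_MODES)), INJECTION_MODES)
  if (length(injections)) {
    bad <- setdiff(names(injections), INJECTION_MODES)
    if (length(bad)) {
      stop_validation(paste("unknown injection mode(s):",
                            paste(bad, collapse = ", ")),
                      "cohortforge_bad_fixture_config")
    }
    inj[names(injections)] <- as.integer(unlist(injections))
  }
  dec <- stats::setNames(rep(0L, length(DECOY_KINDS)), DECOY_KINDS)
  if (length(decoys)) {
    bad <- setdiff(names(decoys), DECOY_KINDS)
    if (length(bad)) {
      stop_validation(paste("unknown decoy kind(s):",
                            paste(bad, collapse = ", ")),
                      "cohortforge_bad_fixture_config")
    }
    dec[names(decoys)] <- as.integer(unlist(decoys))
  }
  if (any(inj < 0L) || any(dec < 0L) || n_patients < 0L ||
      n_extra_exams < 0L) {
    stop_validation("all fixture counts must be non-negative",
                    "cohortforge_bad_fixture_config")
  }
  if (sum(inj) > n_patients) {
    stop_validation(sprintf(
      "injection counts (%d) exceed the number of cohort exams (%d)",
      sum(inj), n_patients), "cohortforge_injection_overflow")
  }
  if (n_extra_exams > n_patients) {
    stop_validation("n_extra_exams may not exceed n_patients (one extra exam per patient at most)",
                    "cohortforge_bad_fixture_config")
  }
  if (date_offset_max < 1L || date_offset_max > 4L) {
    stop_validation("date_offset_max must be in [1, 4]",
                    "cohortforge_bad_fixture_config")
  }
  if (length(hospitals) < 1L) {
    stop_validation("at least one hospital is required",
                    "cohortforge_bad_fixture_config")
  }
  structure(list(seed = as.integer(seed),
                 n_patients = as.integer(n_patients),
                 n_extra_exams = as.integer(n_extra_exams),
                 injections = inj,
                 decoys = dec,
                 hospitals = hospitals,
                 mrn_pad_width = as.integer(mrn_pad_width),
                 acc_strip_prefix = acc_strip_prefix,
                 date_offset_max = as.integer(date_offset_max),
                 n_clean_rendered = as.integer(n_clean_rendered)),
            class = "fixture_config")
}

#' Site rules matching a fixture configuration
#'
#' @param config a [fixture_config()].
#' @return A [site_rules()] table: the first (corrupting) site pads MRNs
#'   and strips the accession prefix; all other sites are identity.
#' @export
fixture_site_rules <- function(config) {
  h <- config$hospitals
  site_rules(h,
             mrn_pad_width = c(config$mrn_pad_width,
                               rep(0L, length(h) - 1L)),
             acc_strip_prefix = c(config$acc_strip_prefix,
                                  rep("", length(h) - 1L)))
}

#' The replica preset
#'
#' A packaged configuration whose injection counts encode the attrition of
#' a published three-hospital abdominal-CT retrieval effort: 33,182
#' filter-surviving exam rows over 23,186 patients; 283 keyword-excludable
#' mislabeled exams; 10,089 exams needing identifier reformatting (6,000
#' dropped-zero MRNs plus 4,089 legacy-prefixed accessions); 838 exams
#' whose image-bearing accession differs from the registry accession (280
#' billing-only, 300 pelvis-linked, 258 chest-linked); 500 exams with a
#' PACS date offset of up to four days; 24 adversarial records the cascade
#' mis-resolves; and 51 non-recoverable failures split 17/7/8/3/1/15
#' across MRN-ACC discrepancy, topogram-only, missing, corrupted,
#' test-patient and encoding-error categories. The preset is constant:
#' repeated calls return identical configurations.
#'
#' @param seed RNG seed (the printed counts are invariant to it; it only
#'   permutes which synthetic exam carries which label).
#' @return A `fixture_config`.
#' @export
paper_replica_config <- function(seed = 20120412L) {
  fixture_config(
    seed = seed,
    n_patients = 23186L,
    n_extra_exams = 9996L,
    injections = list(
      mislabeled_interventional = 283L,
      mrn_zero_dropped = 6000L,
      acc_prefix_added = 4089L,
      billing_only_acc = 280L,
      linkage_pelvis = 300L,
      linkage_chest = 258L,
      date_offset = 500L,
      mrn_acc_discrepancy = 17L,
      topogram_only = 7L,
      missing = 8L,
      corrupted = 3L,
      test_patient = 1L,
      encoding_error = 15L,
      adversarial_misresolution = 24L),
    decoys = list(inpatient = 100L, wrong_year = 100L, age_low = 50L,
                  age_high = 50L, excluded_group = 100L, non_ct = 50L,
                  no_abd = 50L),
    hospitals = c("site_a", "site_b", "site_c"),
    n_clean_rendered = 10L)
}

#' Generate the synthetic registry export and ground truth
#'
#' Deterministic given the config seed. The registry holds one row per
#' exam with *raw* identifiers (zeros dropped, legacy prefix added at the
#' corrupting site); the ground truth records, per exam key (registry
#' `patient_id` + canonical accession), the injected failure mode, the
#' accession that actually carries the images (NA when the exam is
#' missing from PACS), and the injected date offset.
#'
#' @param config a [fixture_config()].
#' @return A list with `registry` and `ground_truth` data.tables.
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, .generate_registry_impl(config))
}

.generate_registry_impl <- function(config) {
  n <- config$n_patients
  inj <- config$injections
  # assign exactly the requested count of each mode to distinct exams
  modes <- rep("none", n)
  if (n > 0L) {
    ord <- sample.int(n)
    pos <- 0L
    for (m in INJECTION_MODES) {
      k <- inj[[m]]
      if (k > 0L) {
        modes[ord[(pos + 1L):(pos + k)]] <- m
        pos <- pos + k
      }
    }
  }

  # canonical 8-digit MRNs: dropped-zero patients draw below 1e7 so the
  # canonical form has a leading zero; everyone else draws above it
  zero_idx <- which(modes == "mrn_zero_dropped")
  mrn_num <- numeric(n)
  if (length(zero_idx)) {
    mrn_num[zero_idx] <- sample.int(9999999L, length(zero_idx))
  }
  rest <- setdiff(seq_len(n), zero_idx)
  if (length(rest)) {
    mrn_num[rest] <- sample.int(80000000L, length(rest)) + 9999999L
  }
  mrn_canon <- sprintf("%08.0f", mrn_num)
  mrn_raw <- mrn_canon
  mrn_raw[zero_idx] <- sub("^0+", "", mrn_canon[zero_idx])

  acc_counter <- 0L
  next_acc <- function(k) {
    out <- sprintf("%.0f", 5000000000 + acc_counter + seq_len(k))
    acc_counter <<- acc_counter + k
    out
  }
  acc_canon <- next_acc(n)
  acc_raw <- acc_canon
  prefix_idx <- which(modes == "acc_prefix_added")
  acc_raw[prefix_idx] <- paste0(config$acc_strip_prefix,
                                acc_canon[prefix_idx])

  hosp <- config$hospitals[sample.int(length(config$hospitals), n,
                                      replace = TRUE)]
  hosp[modes %in% c("mrn_zero_dropped", "acc_prefix_added")] <-
    config$hospitals[1L]

  exam_date <- as.Date("2012-01-01") + sample.int(300L, n, replace = TRUE) - 1L
  exam_time <- sprintf("%02d:%02d:%02d",
                       sample(0:23, n, replace = TRUE),
                       sample(0:59, n, replace = TRUE),
                       sample(0:59, n, replace = TRUE))
  exam_time[runif(n) > 0.9] <- ""
  desc <- sample(.clean_descriptions, n, replace = TRUE)
  mis_idx <- which(modes == "mislabeled_interventional")
  desc[mis_idx] <- sample(.mislabeled_descriptions, length(mis_idx),
                          replace = TRUE)

  registry <- data.table(
    patient_id = mrn_raw,
    accession = acc_raw,
    hospital = hosp,
    exam_date = as.character(exam_date),
    exam_time = exam_time,
    exam_description = desc,
    exam_group = "abdomen",
    modality = "CT",
    patient_type = sample(c("outpatient", "emergency"), n, replace = TRUE,
                          prob = c(0.85, 0.15)),
    age = sample(18:99, n, replace = TRUE),
    exam_code = sprintf("CTAB%02d", sample.int(20L, n, replace = TRUE)))

  # ground truth for the primary (earliest) exams
  needs_alt <- modes %in% c("billing_only_acc", "linkage_pelvis",
                            "linkage_chest", "adversarial_misresolution")
  true_acc <- acc_canon
  true_acc[needs_alt] <- next_acc(sum(needs_alt))
  true_acc[modes == "missing"] <- NA_character_
  off_idx <- which(modes == "date_offset")
  offsets <- rep(NA_integer_, n)
  if (length(off_idx)) {
    m <- config$date_offset_max
    offsets[off_idx] <- sample(c(-(1:m), 1:m), length(off_idx),
                               replace = TRUE)
  }
  ground_truth <- data.table(
    patient_id = mrn_raw,
    registry_accession = acc_canon,
    injected_mode = modes,
    true_accession = true_acc,
    offset_days = offsets,
    mrn_canonical = mrn_canon,
    hospital = hosp,
    exam_date = as.character(exam_date))

  # later exams for a subset of patients (removed by earliest-exam
  # selection; at least 5 days later so they never enter the +/-4 window)
  n_extra <- config$n_extra_exams
  if (n_extra > 0L) {
    who <- sample.int(n, n_extra)
    e_acc <- next_acc(n_extra)
    e_date <- exam_date[who] + sample(5:60, n_extra, replace = TRUE)
    extra <- data.table(
      patient_id = mrn_raw[who],
      accession = e_acc,
      hospital = hosp[who],
      exam_date = as.character(e_date),
      exam_time = sprintf("%02d:%02d:00",
                          sample(0:23, n_extra, replace = TRUE),
                          sample(0:59, n_extra, replace = TRUE)),
      exam_description = sample(.clean_descriptions, n_extra,
                                replace = TRUE),
      exam_group = "abdomen",
      modality = "CT",
      patient_type = "outpatient",
      age = registry$age[who],
      exam_code = sprintf("CTAB%02d", sample.int(20L, n_extra,
                                                 replace = TRUE)))
    registry <- rbindlist(list(registry, extra))
    ground_truth <- rbindlist(list(ground_truth, data.table(
      patient_id = mrn_raw[who],
      registry_accession = e_acc,
      injected_mode = "none",
      true_accession = e_acc,
      offset_days = NA_integer_,
      mrn_canonical = mrn_canon[who],
      hospital = hosp[who],
      exam_date = as.character(e_date))))
  }

  # decoy rows: each fails exactly one upstream registry filter
  dec <- config$decoys
  n_dec <- sum(dec)
  if (n_dec > 0L) {
    kind <- rep(names(dec), times = dec)
    d_mrn <- sprintf("%08.0f",
                     sample.int(10000000L, n_dec) + 89999999L)
    d_date <- as.Date("2012-01-01") +
      sample.int(300L, n_dec, replace = TRUE) - 1L
    d_date[kind == "wrong_year"] <-
      d_date[kind == "wrong_year"] + 366L * sample(c(-1L, 1L),
                                                   sum(kind == "wrong_year"),
                                                   replace = TRUE)
    d_age <- sample(18:99, n_dec, replace = TRUE)
    d_age[kind == "age_low"] <- sample(1:17, sum(kind == "age_low"),
                                       replace = TRUE)
    d_age[kind == "age_high"] <- sample(100:105, sum(kind == "age_high"),
                                        replace = TRUE)
    d_group <- rep("abdomen", n_dec)
    d_group[kind == "excluded_group"] <-
      sample(c("chest", "hdnk", "unclassified", "resp", "lextr", "cspin"),
             sum(kind == "excluded_group"), replace = TRUE)
    d_mod <- rep("CT", n_dec)
    d_mod[kind == "non_ct"] <- sample(c("MR", "US"), sum(kind == "non_ct"),
                                      replace = TRUE)
    d_type <- rep("outpatient", n_dec)
    d_type[kind == "inpatient"] <- "inpatient"
    d_desc <- sample(.clean_descriptions, n_dec, replace = TRUE)
    d_desc[kind == "no_abd"] <- "CT CHEST W CONTRAST"
    d_acc <- next_acc(n_dec)
    decoy <- data.table(
      patient_id = d_mrn,
      accession = d_acc,
      hospital = config$hospitals[sample.int(length(config$hospitals),
                                             n_dec, replace = TRUE)],
      exam_date = as.character(d_date),
      exam_time = "",
      exam_description = d_desc,
      exam_group = d_group,
      modality = d_mod,
      patient_type = d_type,
      age = d_age,
      exam_code = "DECOY")
    registry <- rbindlist(list(registry, decoy))
    ground_truth <- rbindlist(list(ground_truth, data.table(
      patient_id = d_mrn,
      registry_accession = d_acc,
      injected_mode = "none",
      true_accession = NA_character_,
      offset_days = NA_integer_,
      mrn_canonical = d_mrn,
      hospital = decoy$hospital,
      exam_date = as.character(d_date))))
  }

  setorderv(registry, c("patient_id", "exam_date", "accession"))
  setorderv(ground_truth, c("patient_id", "registry_accession"))
  list(registry = registry[], ground_truth = ground_truth[])
}

#' Generate the per-hospital PACS study indices
#'
#' Builds the study rows the clinical archives would hold for the
#' generated cohort, in canonical identifier form, with body part, study
#' date and image count dictated by each exam's injected mode: the true
#' image-bearing study always carries more than 20 images; billing-only
#' and partially-imported accessions carry 20 or fewer; pelvis/chest
#' linkage puts the images under a pelvis or chest study; date offsets
#' shift the study date; discrepancy accessions are filed under a foreign
#' MRN; missing exams have no row at all.
#'
#' @param registry,ground_truth output of [generate_registry()] (same
#'   run).
#' @param config the same [fixture_config()].
#' @return A data.table with columns `hospital`, `mrn`, `accession`,
#'   `study_date`, `body_part`, `modality`, `image_count`.
#' @export
generate_pacs_index <- function(registry, ground_truth, config) {
  stopifnot(inherits(config, "fixture_config"))
  assert_columns(ground_truth, c("patient_id", "registry_accession",
                                 "injected_mode", "true_accession",
                                 "mrn_canonical", "hospital", "exam_date"),
                 "ground truth")
  if (!all(ground_truth$patient_id %in% registry$patient_id)) {
    stop_validation("ground truth references exam keys absent from the registry",
                    "cohortforge_dangling_exam_key")
  }
  with_seed(config$seed + 1L, {
    gt <- as.data.table(ground_truth)
    rows <- list()
    add <- function(hospital, mrn, accession, study_date, body_part,
                    image_count) {
      rows[[length(rows) + 1L]] <<- data.table(
        hospital = hospital, mrn = mrn, accession = accession,
        study_date = as.character(study_date), body_part = body_part,
        modality = "CT", image_count = as.integer(image_count))
    }
    abd <- function(k) sample(.abd_spellings, k, replace = TRUE)
    big <- function(k) sample(40:400, k, replace = TRUE)
    small <- function(k) sample(0:15, k, replace = TRUE)

    # decoys have no PACS rows; missing exams have no PACS rows
    g <- gt[!injected_mode %in% "missing" & !is.na(true_accession)]

    plain <- g[injected_mode %in% c("none", "mislabeled_interventional",
                                    "mrn_zero_dropped", "acc_prefix_added",
                                    "topogram_only", "corrupted",
                                    "test_patient", "encoding_error")]
    if (nrow(plain)) {
      add(plain$hospital, plain$mrn_canonical, plain$registry_accession,
          plain$exam_date, abd(nrow(plain)), big(nrow(plain)))
    }

    offd <- g[injected_mode == "date_offset"]
    if (nrow(offd)) {
      add(offd$hospital, offd$mrn_canonical, offd$registry_accession,
          as.Date(offd$exam_date) + offd$offset_days,
          abd(nrow(offd)), big(nrow(offd)))
    }

    bill <- g[injected_mode == "billing_only_acc"]
    if (nrow(bill)) {
      # registry accession: billing shell with no images
      add(bill$hospital, bill$mrn_canonical, bill$registry_accession,
          bill$exam_date, abd(nrow(bill)), 0L)
      add(bill$hospital, bill$mrn_canonical, bill$true_accession,
          bill$exam_date, abd(nrow(bill)), big(nrow(bill)))
    }

    pelv <- g[injected_mode == "linkage_pelvis"]
    if (nrow(pelv)) {
      # registry accession exists but is a partial import (<= 20 images)
      add(pelv$hospital, pelv$mrn_canonical, pelv$registry_accession,
          pelv$exam_date, abd(nrow(pelv)), small(nrow(pelv)))
      add(pelv$hospital, pelv$mrn_canonical, pelv$true_accession,
          pelv$exam_date,
          sample(.pelvis_spellings, nrow(pelv), replace = TRUE),
          big(nrow(pelv)))
    }

    ches <- g[injected_mode == "linkage_chest"]
    if (nrow(ches)) {
      add(ches$hospital, ches$mrn_canonical, ches$registry_accession,
          ches$exam_date, abd(nrow(ches)), small(nrow(ches)))
      add(ches$hospital, ches$mrn_canonical, ches$true_accession,
          ches$exam_date,
          sample(.chest_spellings, nrow(ches), replace = TRUE),
          big(nrow(ches)))
    }

    adv <- g[injected_mode == "adversarial_misresolution"]
    if (nrow(adv)) {
      # decoy abdomen study on the exam date outranks the true
      # pelvis-linked study in the cascade
      add(adv$hospital, adv$mrn_canonical, adv$registry_accession,
          adv$exam_date, abd(nrow(adv)), sample(25:39, nrow(adv),
                                                replace = TRUE))
      add(adv$hospital, adv$mrn_canonical, adv$true_accession,
          adv$exam_date,
          sample(.pelvis_spellings, nrow(adv), replace = TRUE),
          big(nrow(adv)))
    }

    disc <- g[injected_mode == "mrn_acc_discrepancy"]
    if (nrow(disc)) {
      # the registry accession is filed under someone else's MRN
      foreign <- sprintf("%08.0f",
                         sample.int(10000000L, nrow(disc)) + 89999999L)
      add(disc$hospital, foreign, disc$registry_accession,
          disc$exam_date, abd(nrow(disc)), big(nrow(disc)))
    }

    index <- rbindlist(rows)
    setorderv(index, c("hospital", "mrn", "accession"))
    index[]
  })
}

#' Build the DICOM retrieval manifest for a fixture
#'
#' Lists the studies to render as DICOM files: every study with an
#' injected content-level failure (topogram-only, corrupted, test-patient,
#' encoding-error) plus the first `n_clean_rendered` clean studies. All
#' other studies exist only as index rows — the fixture's stand-in for a
#' retrieval where pixel data is staged for a subset.
#'
#' @param ground_truth ground truth from [generate_registry()].
#' @param config the [fixture_config()].
#' @return data.table with `accession`, `mode`, `patient_id` (canonical
#'   MRN), `patient_name`, `study_date`, `n_instances`.
#' @export
fixture_manifest <- function(ground_truth, config) {
  gt <- as.data.table(ground_truth)
  fail <- gt[injected_mode %in% CONTENT_FAILURE_MODES]
  clean <- gt[injected_mode == "none" & !is.na(true_accession)]
  setorderv(clean, "registry_accession")
  clean <- head(clean, config$n_clean_rendered)
  man <- rbindlist(list(fail, clean))
  man[, mode := fifelse(injected_mode %in% CONTENT_FAILURE_MODES,
                        injected_mode, "none")]
  out <- man[, .(accession = true_accession, mode,
                 patient_id = mrn_canonical,
                 patient_name = fifelse(
                   mode == "test_patient", "ZZZ^TEST^PHANTOM",
                   paste0("SYNTH^P", mrn_canonical)),
                 study_date = exam_date,
                 n_instances = fifelse(mode == "topogram_only", 2L, 4L))]
  setorderv(out, "accession")
  out[]
}

#' Generate a complete fixture
#'
#' Runs [generate_registry()], [generate_pacs_index()] and
#' [fixture_manifest()], then verifies the adversarial construction by
#' running the resolution cascade on the adversarial exams: generation
#' fails loudly if any of them would in fact resolve to its true
#' accession.
#'
#' @param config a [fixture_config()].
#' @return A list: `registry`, `ground_truth`, `pacs_index`, `manifest`,
#'   `site_rules`, `config`.
#' @export
generate_fixture <- function(config = fixture_config()) {
  reg <- generate_registry(config)
  index <- generate_pacs_index(reg$registry, reg$ground_truth, config)
  manifest <- fixture_manifest(reg$ground_truth, config)
  rules <- fixture_site_rules(config)

  gt <- as.data.table(reg$ground_truth)
  adv <- gt[injected_mode == "adversarial_misresolution"]
  if (nrow(adv)) {
    cohort <- adv[, .(patient_id, accession_canonical = registry_accession,
                      mrn_canonical, exam_date)]
    res <- resolve_cohort(cohort, index)
    chk <- flag_misresolutions(res, adv)
    if (chk$n != nrow(adv)) {
      stop_validation(sprintf(
        "adversarial construction failed: %d of %d records mis-resolve",
        chk$n, nrow(adv)), "cohortforge_fixture_construction")
    }
  }
  list(registry = reg$registry, ground_truth = reg$ground_truth,
       pacs_index = index, manifest = manifest, site_rules = rules,
       config = config)
}

#' Write a fixture to disk
#'
#' Emits `registry.csv` (RFC-4180), one `pacs_<hospital>.csv` per site,
#' `ground_truth.csv`, `manifest.csv`, `site_rules.csv` and
#' `config.json`; with `render_dicom = TRUE` also renders the manifest
#' studies under `dir/dicom/<accession>/`.
#'
#' @param fixture output of [generate_fixture()].
#' @param dir output directory (created if needed).
#' @param render_dicom also write the DICOM files.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir, render_dicom = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(fixture$registry, file.path(dir, "registry.csv"))
  fwrite(fixture$ground_truth, file.path(dir, "ground_truth.csv"))
  fwrite(fixture$manifest, file.path(dir, "manifest.csv"))
  fwrite(fixture$site_rules, file.path(dir, "site_rules.csv"))
  for (h in unique(fixture$pacs_index$hospital)) {
    fwrite(fixture$pacs_index[fixture$pacs_index$hospital == h,
                              c("mrn", "accession", "study_date",
                                "body_part", "modality", "image_count")],
           file.path(dir, sprintf("pacs_%s.csv", h)))
  }
  cfg <- unclass(fixture$config)
  cfg$injections <- as.list(cfg$injections)
  cfg$decoys <- as.list(cfg$decoys)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (render_dicom) {
    render_dicom_fixtures(fixture$manifest, file.path(dir, "dicom"))
  }
  invisible(dir)
}
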