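#' Registry cohort filter configuration
#'
#' The research-registry export contains every radiology exam for every
#' patient who had at least one qualifying CT, so the first step is a set
#' of row filters: modality, exam year, a required description substring,
#' excluded exam groups, excluded patient types, and an inclusive age
#' range. Defaults reproduce an adult outpatient abdominal-CT selection:
#' CT only, imaged in 2012, description containing "Abd", exam group not
#' chest/head-and-neck/unclassified/respiratory/lower-extremity/cervical-
#' spine, patient type not inpatient, age 18-99 inclusive.
#'
#' The `exclusion_keywords` are applied later, by
#' [apply_keyword_exclusion()], to remove mislabeled interventional and
#' musculoskeletal exams; matching is case-insensitive substring matching
#' (so "drainage" is matched by "drain" and is retained in the list only
#' for fidelity to common local practice).
#'
#' @param modality character vector of allowed modalities.
#' @param year integer vector of allowed exam years.
#' @param description_substring required substring in the exam description
#'   (case-insensitive).
#' @param excluded_groups exam groups to drop.
#' @param excluded_patient_types patient types to drop.
#' @param age_range inclusive `[min, max]` age in years.
#' @param exclusion_keywords keywords flagging mislabeled exams.
#' @return A list of class `cohort_filter_config`.
#' @export
cohort_filter_config <- function(
    modality = "CT",
    year = 2012L,
    description_substring = "Abd",
    excluded_groups = c("chest", "hdnk", "unclassified", "resp",
                        "lextr", "cspin"),
    excluded_patient_types = "inpatient",
    age_range = c(18L, 99L),
    exclusion_keywords = c("ablation", "fna", "biopsy", "drainage",
                           "guidance", "drain", "drg", "bx",
                           "interventional", "interv", "perc", "bone")) {
  if (length(age_range) != 2L || age_range[1] > age_range[2]) {
    stop_validation("age_range must be c(min, max) with min <= max",
                    "cohortforge_bad_filter_config")
  }
  if (!length(exclusion_keywords)) {
    stop_validation("exclusion keyword list must be non-empty",
                    "cohortforge_bad_filter_config")
  }
  structure(list(
    modality = modality,
    year = as.integer(year),
    description_substring = description_substring,
    excluded_groups = tolower(excluded_groups),
    excluded_patient_types = tolower(excluded_patient_types),
    age_range = as.integer(age_range),
    exclusion_keywords = tolower(exclusion_keywords)
  ), class = "cohort_filter_config")
}

#' Apply the registry row filters
#'
#' A record is kept if and only if it passes every filter in the
#' configuration. Records with an unparseable exam date or age are not
#' silently dropped: they are quarantined in a rejects table with a reason,
#' so stage counts always telescope. Input order is preserved in all three
#' partitions.
#'
#' @param records registry export as a data.frame (see
#'   [generate_registry()] for the column contract).
#' @param config a [cohort_filter_config()].
#' @return A list with `kept`, `removed` (with a `reason` column naming the
#'   first failed filter), and `rejects` (malformed rows, with `reason`).
#' @export
apply_registry_filters <- function(records, config = cohort_filter_config()) {
  assert_columns(records, c("patient_id", "accession", "hospital",
                            "exam_date", "exam_description", "exam_group",
                            "modality", "patient_type", "age"),
                 "registry export")
  dt <- as.data.table(records)
  if (!nrow(dt)) {
    return(list(kept = dt, removed = dt, rejects = dt))
  }
  date_parsed <- as_date_safe(dt$exam_date)
  age_num <- suppressWarnings(as.integer(dt$age))
  malformed <- is.na(date_parsed) | is.na(age_num)
  rejects <- dt[malformed]
  if (nrow(rejects)) {
    rejects[, reason := ifelse(is.na(date_parsed[malformed]),
                               "unparseable exam_date", "unparseable age")]
  } else {
    rejects[, reason := character(0)]
  }

  ok <- dt[!malformed]
  dts <- date_parsed[!malformed]
  ages <- age_num[!malformed]
  why_failed <- rep(NA_character_, nrow(ok))
  fail <- function(cond, why) {
    hit <- is.na(why_failed) & cond
    why_failed[hit] <<- why
  }
  fail(!(ok$modality %in% config$modality), "modality")
  fail(!(as.integer(format(dts, "%Y")) %in% config$year), "year")
  fail(!grepl(config$description_substring, ok$exam_description,
              ignore.case = TRUE, fixed = FALSE),
       "description_substring")
  fail(tolower(ok$exam_group) %in% config$excluded_groups, "exam_group")
  fail(tolower(ok$patient_type) %in% config$excluded_patient_types,
       "patient_type")
  fail(ages < config$age_range[1] | ages > config$age_range[2], "age")

  removed <- ok[!is.na(why_failed)]
  removed[, reason := why_failed[!is.na(why_failed)]]
  list(kept = ok[is.na(why_failed)],
       removed = removed,
       rejects = rejects)
}

#' Select the earliest exam per patient
#'
#' Reduces the filtered registry to one exam per patient: the earliest by
#' exam date, with ties broken by exam time (records with a recorded time
#' sort before records without one) and then by lexicographic accession.
#' The result is independent of input row order.
#'
#' @param records filtered registry records.
#' @return One record per distinct `patient_id`.
#' @export
select_earliest_per_patient <- function(records) {
  assert_columns(records, c("patient_id", "accession", "exam_date"),
                 "filtered records")
  dt <- as.data.table(records)
  if (!nrow(dt)) return(dt)
  tm <- if ("exam_time" %in% names(dt)) as.character(dt$exam_time) else
    rep(NA_character_, nrow(dt))
  tm[is.na(tm) | !nzchar(tm)] <- "~"  # '~' sorts after any HH:MM:SS digit
  ord <- order(dt$patient_id, as_date_safe(dt$exam_date), tm, dt$accession,
               method = "radix")
  dt <- dt[ord]
  dt[!duplicated(patient_id)]
}

#' Exclude mislabeled exams by description keyword
#'
#' Registry exam groups are unreliable: interventional and musculoskeletal
#' CTs are sometimes labeled abdominal. A record is excluded if and only if
#' its description, lowercased, contains any keyword as a substring. The
#' two partitions cover the input exactly.
#'
#' @param records one-per-patient cohort records.
#' @param keywords character vector of lowercase keywords.
#' @return A list with `kept` and `excluded` data.tables.
#' @export
apply_keyword_exclusion <- function(
    records,
    keywords = cohort_filter_config()$exclusion_keywords) {
  assert_columns(records, "exam_description", "cohort records")
  dt <- as.data.table(records)
  if (!nrow(dt)) return(list(kept = dt, excluded = dt))
  desc <- tolower(dt$exam_description)
  hit <- rep(FALSE, nrow(dt))
  for (kw in tolower(keywords)) {
    hit <- hit | grepl(kw, desc, fixed = TRUE)
  }
  list(kept = dt[!hit], excluded = dt[hit])
}
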