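#' Triage configuration
#'
#' @param test_name_patterns substrings (case-insensitive) of PatientName
#'   that mark non-patient test exams.
#' @param max_localizer_instances a study whose decodable instances are
#'   all localizers counts as topogram-only when it has at most this many
#'   instances.
#' @return A list of class `triage_config`.
#' @export
triage_config <- function(test_name_patterns = c("TEST", "PHANTOM", "ZZZ"),
                          max_localizer_instances = 5L) {
  structure(list(test_name_patterns = toupper(test_name_patterns),
                 max_localizer_instances = as.integer(
                   max_localizer_instances)),
            class = "triage_config")
}

# Content-level triage of one rendered study directory; returns NULL when
# the study passes every content check.
.triage_content <- function(study_dir, config) {
  if (!dir.exists(study_dir)) {
    return(list(disposition = "failed_missing",
                evidence = "listed in retrieval manifest but no study directory on disk"))
  }
  s <- dicom_read_study(study_dir)
  if (s$n_files == 0L) {
    return(list(disposition = "failed_missing",
                evidence = "study directory contains no instances"))
  }
  if (s$any_encoding_error) {
    return(list(disposition = "failed_encoding",
                evidence = "undecodable DICOM metadata in at least one instance"))
  }
  if (s$any_pixel_failure) {
    return(list(disposition = "failed_corrupted",
                evidence = "pixel payload fails to decode while metadata parses"))
  }
  if (s$all_localizer && s$n_decoded <= config$max_localizer_instances) {
    return(list(disposition = "failed_topogram_only",
                evidence = "every decodable instance is a localizer"))
  }
  names_up <- toupper(s$patient_names)
  for (pat in config$test_name_patterns) {
    if (any(grepl(pat, names_up, fixed = TRUE))) {
      return(list(disposition = "failed_test_patient",
                  evidence = sprintf("patient name matches test pattern '%s'", pat)))
    }
  }
  NULL
}

#' Triage one exam into a final disposition
#'
#' Applies the failure checks in a fixed precedence order, so multi-fault
#' exams land in exactly one category: MRN/ACC discrepancy (the PACS MRN
#' recorded for the exam's accession conflicts with the canonical registry
#' MRN), then missing (no resolvable study), then — for studies whose
#' files were retrieved — encoding error, corrupted pixel data,
#' topogram-only and non-patient test exam; an exam clearing every check
#' is included. Identifier-level faults deliberately dominate
#' content-level faults.
#'
#' @param resolution one-row resolution result for the exam (from
#'   [resolve_cohort()], possibly after overrides).
#' @param mrn_canonical the exam's canonical registry MRN.
#' @param index combined PACS study index.
#' @param study_dir directory of retrieved DICOM files for the chosen
#'   accession, or `NA`/`NULL` when the study was not retrieved (content
#'   checks are then skipped).
#' @param config a [triage_config()].
#' @return A list with `disposition` and `evidence`.
#' @export
triage_study <- function(resolution, mrn_canonical, index,
                         study_dir = NULL, config = triage_config()) {
  idx <- as.data.table(index)
  acc <- if (identical(resolution$status, "resolved"))
    resolution$chosen_accession else resolution$registry_accession
  pacs_mrns <- unique(idx$mrn[idx$accession == acc])
  if (length(pacs_mrns) && !mrn_canonical %in% pacs_mrns) {
    return(list(disposition = "failed_mrn_acc_discrepancy",
                evidence = sprintf(
                  "PACS holds accession %s under MRN %s, registry says %s",
                  acc, paste(pacs_mrns, collapse = "/"), mrn_canonical)))
  }
  if (!identical(resolution$status, "resolved")) {
    return(list(disposition = "failed_missing",
                evidence = "no resolvable study in any PACS index"))
  }
  if (!is.null(study_dir) && !is.na(study_dir)) {
    content <- .triage_content(study_dir, config)
    if (!is.null(content)) return(content)
  }
  list(disposition = "included", evidence = "")
}

#' Triage every cohort exam
#'
#' Vectorized driver over [triage_study()]'s rules. Identifier-level
#' checks run on the full cohort from the index alone; content-level
#' checks run for the exams whose studies appear in the retrieval
#' `manifest` (accessions mapped to directories under `dicom_root`).
#' Exams outside the manifest pass content checks vacuously — the
#' metadata-only mode used when pixel data is not staged locally.
#'
#' @param results resolution results (post-override) for the cohort.
#' @param cohort cohort records carrying `patient_id`,
#'   `accession_canonical`, `mrn_canonical`.
#' @param index combined PACS study index.
#' @param dicom_root root directory of rendered/retrieved studies, or
#'   `NULL`.
#' @param manifest data.frame with an `accession` column listing the
#'   retrieved studies (directory `dicom_root/<accession>`), or `NULL`.
#' @param config a [triage_config()].
#' @return data.table of disposition records: `patient_id`,
#'   `registry_accession`, `disposition`, `evidence`.
#' @export
triage_cohort <- function(results, cohort, index, dicom_root = NULL,
                          manifest = NULL, config = triage_config()) {
  res <- as.data.table(results)
  co <- as.data.table(cohort)[, .(patient_id,
                                  registry_accession = accession_canonical,
                                  mrn_canonical)]
  dt <- co[res, on = c("patient_id", "registry_accession")]
  idx <- as.data.table(index)[, .(accession, mrn)]

  # identifier-level checks, whole cohort at once
  dt[, acc_lookup := fifelse(status == "resolved", chosen_accession,
                             registry_accession)]
  pacs <- idx[, .(pacs_mrns = list(unique(mrn))), by = accession]
  dt <- pacs[dt, on = c(accession = "acc_lookup")]
  setnames(dt, "accession", "acc_lookup")
  has_pacs <- !vapply(dt$pacs_mrns, is.null, logical(1))
  mrn_conflict <- has_pacs & !mapply(function(m, ms) m %in% ms,
                                     dt$mrn_canonical, dt$pacs_mrns)
  dt[, disposition := "included"]
  dt[, evidence := ""]
  dt[mrn_conflict, `:=`(
    disposition = "failed_mrn_acc_discrepancy",
    evidence = "PACS MRN for the matched accession conflicts with registry MRN")]
  dt[disposition == "included" & status != "resolved", `:=`(
    disposition = "failed_missing",
    evidence = "no resolvable study in any PACS index")]

  # content-level checks for retrieved studies only
  if (!is.null(manifest) && nrow(manifest) && !is.null(dicom_root)) {
    man_acc <- unique(as.character(manifest$accession))
    todo <- which(dt$disposition == "included" & dt$status == "resolved" &
                    dt$chosen_accession %in% man_acc)
    for (i in todo) {
      content <- .triage_content(
        file.path(dicom_root, dt$chosen_accession[i]), config)
      if (!is.null(content)) {
        dt[i, `:=`(disposition = content$disposition,
                   evidence = content$evidence)]
      }
    }
  }
  out <- dt[, .(patient_id, registry_accession, disposition, evidence)]
  setorderv(out, c("patient_id", "registry_accession"))
  out[]
}

#' Build the stage-by-stage attrition report
#'
#' Assembles the telescoping account of how the initial registry export
#' shrinks to the final dataset: upstream filter removals, earliest-exam
#' reduction, keyword exclusions, and each non-recoverable failure
#' category. The telescoping identity (each stage's input equals its
#' output plus its removals) is verified and a violation is a hard error
#' carrying the offending stage.
#'
#' @param dispositions disposition records for the post-exclusion cohort
#'   (from [triage_cohort()]).
#' @param stage_counts named list with `registry_rows`, `filter_removed`,
#'   `filter_rejects`, `filter_kept`, `patients_selected`,
#'   `keyword_excluded`.
#' @return A list of class `attrition_report` with `stages` (data.frame:
#'   `stage`, `count`) and `failure_counts` (named integer vector).
#' @export
build_attrition_report <- function(dispositions, stage_counts) {
  need <- c("registry_rows", "filter_removed", "filter_rejects",
            "filter_kept", "patients_selected", "keyword_excluded")
  missing <- setdiff(need, names(stage_counts))
  if (length(missing)) {
    stop_validation(paste("stage_counts missing:",
                          paste(missing, collapse = ", ")),
                    "cohortforge_bad_stage_counts")
  }
  sc <- lapply(stage_counts, as.integer)
  if (sc$registry_rows !=
      sc$filter_kept + sc$filter_removed + sc$filter_rejects) {
    stop_validation("registry filter stage does not telescope",
                    "cohortforge_conservation_failure")
  }
  dis <- as.data.table(dispositions)
  cohort_n <- sc$patients_selected - sc$keyword_excluded
  if (nrow(dis) != cohort_n) {
    stop_validation(sprintf(
      "disposition partition violation: %d dispositions for %d cohort exams",
      nrow(dis), cohort_n), "cohortforge_conservation_failure")
  }
  cats <- c("failed_mrn_acc_discrepancy", "failed_topogram_only",
            "failed_missing", "failed_corrupted", "failed_test_patient",
            "failed_encoding")
  fc <- vapply(cats, function(d) sum(dis$disposition == d), integer(1))
  n_included <- sum(dis$disposition == "included")
  if (n_included + sum(fc) != cohort_n) {
    bad <- dis[!disposition %in% c(cats, "included")]
    stop_validation(paste("unknown dispositions for exam keys:",
                          paste(utils::head(bad$patient_id, 5L),
                                collapse = ", ")),
                    "cohortforge_conservation_failure")
  }
  stages <- data.frame(
    stage = c("registry rows", "removed by registry filters",
              "malformed rows quarantined", "exams passing filters",
              "earliest exam per patient", "excluded by keyword",
              "cohort entering retrieval",
              paste0("non-recoverable: ", sub("^failed_", "", cats)),
              "final valid exams"),
    count = c(sc$registry_rows, sc$filter_removed, sc$filter_rejects,
              sc$filter_kept, sc$patients_selected, sc$keyword_excluded,
              cohort_n, unname(fc), n_included),
    stringsAsFactors = FALSE)
  structure(list(stages = stages, failure_counts = fc,
                 n_included = n_included, n_non_recoverable = sum(fc)),
            class = "attrition_report")
}

#' @export
print.attrition_report <- function(x, ...) {
  cat("Cohort attrition\n")
  w <- max(nchar(x$stages$stage))
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-*s %9s\n", w, x$stages$stage[i],
                format(x$stages$count[i], big.mark = ",")))
  }
  invisible(x)
}

#' @export
format.attrition_report <- function(x, ...) {
  paste(utils::capture.output(print(x)), collapse = "\n")
}
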