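#' Configure an end-to-end pipeline run
#'
#' Inputs may be in-memory data.frames (as produced by
#' [generate_fixture()]) or paths to the corresponding CSV files.
#'
#' @param registry registry export (data.frame or CSV path).
#' @param pacs_index combined PACS index (data.frame), or a character
#'   vector of per-hospital CSV paths (a missing `hospital` column is
#'   filled from each file name's `pacs_<hospital>.csv` stem).
#' @param site_rules a [site_rules()] table or CSV path.
#' @param filter_config a [cohort_filter_config()].
#' @param triage_config a [triage_config()].
#' @param dicom_root root directory of retrieved DICOM studies, or `NULL`.
#' @param manifest retrieval manifest (data.frame or CSV path), or `NULL`.
#' @param ground_truth fixture ground truth (data.frame or CSV path), or
#'   `NULL`; when present, mis-resolutions are scored and replayed as
#'   manual corrections.
#' @param out_dir directory for stage artifacts, or `NULL` to skip
#'   writing.
#' @param seed integer recorded in every report (the pipeline itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(registry, pacs_index, site_rules,
                            filter_config = cohort_filter_config(),
                            triage_config = cohortforge::triage_config(),
                            dicom_root = NULL, manifest = NULL,
                            ground_truth = NULL, out_dir = NULL,
                            seed = 1L) {
  structure(list(registry = registry, pacs_index = pacs_index,
                 site_rules = site_rules, filter_config = filter_config,
                 triage_config = triage_config, dicom_root = dicom_root,
                 manifest = manifest, ground_truth = ground_truth,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

.load_table <- function(x, what, char_cols = NULL, na_to_empty = FALSE) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) {
      stop_validation(sprintf("%s file not found: %s", what, x),
                      "cohortforge_missing_input")
    }
    hdr <- names(fread(x, nrows = 0L))
    want <- intersect(char_cols, hdr)
    x <- if (length(want)) fread(x, colClasses = list(character = want))
         else fread(x)
  }
  dt <- as.data.table(x)
  for (col in intersect(char_cols, names(dt))) {
    v <- as.character(dt[[col]])
    if (na_to_empty) v[is.na(v)] <- ""
    dt[, (col) := v]
  }
  dt
}

.load_pacs <- function(x) {
  if (is.data.frame(x)) return(as.data.table(x))
  parts <- lapply(x, function(p) {
    dt <- .load_table(p, "PACS index", char_cols = c("mrn", "accession"))
    if (!"hospital" %in% names(dt)) {
      dt[, hospital := sub("^pacs_(.*)\\.csv$", "\\1", basename(p))]
    }
    dt
  })
  rbindlist(parts, use.names = TRUE, fill = TRUE)
}

#' Run the full curation pipeline
#'
#' Executes select (registry filters + earliest exam per patient) ->
#' exclude (description keywords) -> normalize (per-site identifiers) ->
#' resolve (PACS accession cascade, with ground-truth-scored manual
#' corrections when available) -> triage (failure categories) -> report
#' (attrition), logging every stage and writing each intermediate as CSV
#' when `out_dir` is set. A conservation failure (stage counts that do not
#' telescope) is a hard error.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result`: `attrition`
#'   (an `attrition_report`), `cohort`, `resolutions` (post-correction),
#'   `dispositions`, `registry_discrepancies`, `misresolutions` (`NULL`
#'   without ground truth), `n_reformatted`, `stage_counts`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, ...) {
    entry <- c(list(stage = stage, seed = config$seed), list(...))
    log[[length(log) + 1L]] <<- entry
  }

  registry <- .load_table(config$registry, "registry",
                          char_cols = c("patient_id", "accession",
                                        "exam_time"), na_to_empty = TRUE)
  index <- .load_pacs(config$pacs_index)
  rules <- .load_table(config$site_rules, "site rules",
                       char_cols = "acc_strip_prefix", na_to_empty = TRUE)
  ground_truth <- .load_table(config$ground_truth, "ground truth",
                              char_cols = c("patient_id",
                                            "registry_accession",
                                            "true_accession",
                                            "mrn_canonical"))
  manifest <- .load_table(config$manifest, "manifest",
                          char_cols = c("accession", "patient_id"))

  filt <- apply_registry_filters(registry, config$filter_config)
  note("select", registry_rows = nrow(registry),
       kept = nrow(filt$kept), removed = nrow(filt$removed),
       rejects = nrow(filt$rejects))

  earliest <- select_earliest_per_patient(filt$kept)
  note("earliest", patients = nrow(earliest))

  excl <- apply_keyword_exclusion(earliest,
                                  config$filter_config$exclusion_keywords)
  note("exclude", excluded = nrow(excl$excluded), kept = nrow(excl$kept))

  norm <- normalize_cohort(excl$kept, rules)
  cohort <- norm$records
  note("normalize", reformatted = norm$n_reformatted,
       non_numeric_mrn = length(norm$non_numeric_mrn))

  resolutions <- resolve_cohort(cohort, index)
  disc <- flag_registry_discrepancies(resolutions)
  note("resolve", resolved = sum(resolutions$status == "resolved"),
       unresolved = sum(resolutions$status == "unresolved"),
       non_registry_accession = disc$n)

  mis <- NULL
  if (!is.null(ground_truth)) {
    mis <- flag_misresolutions(resolutions, ground_truth)
    resolutions <- apply_resolution_overrides(resolutions, mis$overrides)
    note("correct", misresolved = mis$n)
  }

  dispositions <- triage_cohort(resolutions, cohort, index,
                                dicom_root = config$dicom_root,
                                manifest = manifest,
                                config = config$triage_config)
  note("triage", included = sum(dispositions$disposition == "included"),
       failed = sum(dispositions$disposition != "included"))

  stage_counts <- list(registry_rows = nrow(registry),
                       filter_removed = nrow(filt$removed),
                       filter_rejects = nrow(filt$rejects),
                       filter_kept = nrow(filt$kept),
                       patients_selected = nrow(earliest),
                       keyword_excluded = nrow(excl$excluded))
  attrition <- build_attrition_report(dispositions, stage_counts)
  note("report", final = attrition$n_included,
       non_recoverable = attrition$n_non_recoverable)

  result <- structure(list(attrition = attrition, cohort = cohort,
                           resolutions = resolutions,
                           dispositions = dispositions,
                           registry_discrepancies = disc,
                           misresolutions = mis,
                           n_reformatted = norm$n_reformatted,
                           stage_counts = stage_counts,
                           log = log,
                           seed = config$seed),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    write_pipeline_artifacts(result, excl$excluded, config$out_dir)
  }
  result
}

# Stage artifacts: every intermediate as CSV, attrition as CSV + JSON,
# decisions as line-delimited JSON.
write_pipeline_artifacts <- function(result, excluded, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(result$cohort, file.path(out_dir, "cohort.csv"))
  fwrite(excluded, file.path(out_dir, "keyword_excluded.csv"))
  fwrite(result$resolutions, file.path(out_dir, "resolutions.csv"))
  fwrite(result$dispositions, file.path(out_dir, "dispositions.csv"))
  fwrite(result$attrition$stages, file.path(out_dir, "attrition.csv"))
  jsonlite::write_json(
    list(seed = result$seed,
         stages = result$attrition$stages,
         failure_counts = as.list(result$attrition$failure_counts),
         n_reformatted = result$n_reformatted,
         n_non_registry_accession = result$registry_discrepancies$n,
         n_misresolved = if (is.null(result$misresolutions)) NULL
                         else result$misresolutions$n,
         final = result$attrition$n_included),
    file.path(out_dir, "attrition.json"), auto_unbox = TRUE, digits = NA)
  writeLines(vapply(result$log, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE), character(1)),
    file.path(out_dir, "log.jsonl"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$attrition)
  cat(sprintf("  identifiers reformatted: %s exams\n",
              format(x$n_reformatted, big.mark = ",")))
  cat(sprintf("  resolved to a non-registry accession: %s exams\n",
              format(x$registry_discrepancies$n, big.mark = ",")))
  if (!is.null(x$misresolutions)) {
    cat(sprintf("  mis-resolved (corrected from ground truth): %s exams\n",
                format(x$misresolutions$n, big.mark = ",")))
  }
  invisible(x)
}

#' Run the replica fixture end to end
#'
#' Convenience wrapper: generates the replica preset fixture (or any
#' supplied config), renders its DICOM manifest under a temporary (or
#' given) directory, and runs the full pipeline with ground-truth
#' correction replay.
#'
#' @param config a [fixture_config()]; defaults to
#'   [paper_replica_config()].
#' @param dicom_dir directory for rendered studies (default: a session
#'   temporary directory).
#' @param out_dir artifact directory, or `NULL`.
#' @return A list with `fixture` and `result` (a `pipeline_result`).
#' @export
run_replica <- function(config = paper_replica_config(),
                        dicom_dir = tempfile("cohortforge_dicom_"),
                        out_dir = NULL) {
  fixture <- generate_fixture(config)
  render_dicom_fixtures(fixture$manifest, dicom_dir)
  pc <- pipeline_config(registry = fixture$registry,
                        pacs_index = fixture$pacs_index,
                        site_rules = fixture$site_rules,
                        dicom_root = dicom_dir,
                        manifest = fixture$manifest,
                        ground_truth = fixture$ground_truth,
                        seed = config$seed,
                        out_dir = out_dir)
  list(fixture = fixture, result = run_pipeline(pc))
}
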