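#' @importFrom data.table := data.table as.data.table setorder setorderv
#'   copy rbindlist setnames fwrite fread setDT fifelse .I .N .SD
#' @importFrom stats runif
#' @importFrom utils head modifyList
NULL

# data.table NSE columns; silences R CMD check notes without masking real ones
utils::globalVariables(c(
  ".", ".N", ".SD", "abs_diff", "accession", "accession_canonical",
  "body_part", "bp_rank", "chosen_accession", "disposition", "exam_date",
  "exam_time", "hospital", "image_count", "injected_mode", "modality",
  "mrn", "mrn_canonical", "patient_id", "priority", "registry_accession",
  "status", "study_date", "tier", "true_accession", "window_used",
  "differs_from_registry", "reformatted", "reason", "age", "exam_group",
  "patient_type", "exam_description", "pick", "n_instances", "mode",
  "patient_name", "i.mrn", "i.true_accession", "i.injected_mode", "keep"
))

# Run code with a temporary RNG state so generators are reproducible
# without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cohortforge_validation_error")))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_validation(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      "cohortforge_bad_input"
    )
  }
}

as_date_safe <- function(x) {
  suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
}
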