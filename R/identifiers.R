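#' Per-site identifier normalization rules
#'
#' Hospitals export medical record numbers (MRNs) and accession numbers
#' (ACCs) in site-specific formats that may not match the canonical form
#' used by the PACS: research-registry exports commonly drop leading zeros
#' from numeric MRNs, and accessions issued before an EMR migration may
#' carry a legacy literal prefix. A rule set states, per site, the MRN
#' zero-pad width and the accession prefix to strip. Rules are data, not
#' code: adding a site means adding a row.
#'
#' @param hospital character vector of site codes.
#' @param mrn_pad_width integer vector; MRNs shorter than this are
#'   left-padded with zeros (0 disables padding). Must be in `[0, 16]`.
#' @param acc_strip_prefix character vector; this literal prefix is removed
#'   at most once from the left of each accession (`""` disables).
#' @return A `data.frame` with columns `hospital`, `mrn_pad_width`,
#'   `acc_strip_prefix`, one row per site.
#' @examples
#' site_rules(c("site_a", "site_b"), c(8L, 0L), c("A", ""))
#' @export
site_rules <- function(hospital, mrn_pad_width = 0L, acc_strip_prefix = "") {
  n <- length(hospital)
  mrn_pad_width <- as.integer(rep_len(mrn_pad_width, n))
  acc_strip_prefix <- as.character(rep_len(acc_strip_prefix, n))
  if (anyNA(mrn_pad_width) || any(mrn_pad_width < 0L | mrn_pad_width > 16L)) {
    stop_validation("mrn_pad_width must be in [0, 16]", "cohortforge_bad_rules")
  }
  if (anyDuplicated(hospital)) {
    stop_validation("duplicate hospital codes in site rules",
                    "cohortforge_bad_rules")
  }
  data.frame(hospital = as.character(hospital),
             mrn_pad_width = mrn_pad_width,
             acc_strip_prefix = acc_strip_prefix,
             stringsAsFactors = FALSE)
}

#' Canonicalize a medical record number
#'
#' Left-pads the MRN with zeros to the configured width; values already at
#' or beyond the width pass through unchanged. Non-numeric MRNs are padded
#' as-is (no digit constraint is imposed). Idempotent.
#'
#' @param mrn character vector of raw MRNs (whitespace is trimmed).
#' @param pad_width integer scalar, zero-pad width (0 = no padding).
#' @return Character vector of canonical MRNs.
#' @examples
#' normalize_mrn("1234567", 8L)  # "01234567"
#' @export
normalize_mrn <- function(mrn, pad_width = 0L) {
  mrn <- trimws(as.character(mrn))
  if (any(is.na(mrn) | !nzchar(mrn))) {
    stop_validation("empty MRN after whitespace trim", "cohortforge_empty_mrn")
  }
  pad_width <- as.integer(pad_width)
  need <- pmax(0L, pad_width - nchar(mrn))
  paste0(strrep("0", need), mrn)
}

#' Canonicalize an accession number
#'
#' Strips the configured literal prefix once, if present at position 0;
#' otherwise the accession is returned unchanged. Idempotent only when the
#' stripped value does not itself start with the prefix (e.g. `"AA123"`
#' becomes `"A123"` on one application, by design: the legacy export added
#' the prefix exactly once).
#'
#' @param acc character vector of raw accessions (whitespace is trimmed).
#' @param strip_prefix character scalar; `""` disables stripping.
#' @return Character vector of canonical accessions.
#' @examples
#' normalize_accession("A1234567", "A")  # "1234567"
#' @export
normalize_accession <- function(acc, strip_prefix = "") {
  acc <- trimws(as.character(acc))
  if (any(is.na(acc) | !nzchar(acc))) {
    stop_validation("empty accession after whitespace trim",
                    "cohortforge_empty_accession")
  }
  if (nzchar(strip_prefix)) {
    hit <- startsWith(acc, strip_prefix)
    acc[hit] <- substring(acc[hit], nchar(strip_prefix) + 1L)
    if (any(is.na(acc) | !nzchar(acc))) {
      stop_validation("accession empty after prefix strip",
                      "cohortforge_empty_accession")
    }
  }
  acc
}

#' Canonicalize identifiers across a cohort
#'
#' Applies the per-site rules to every record, carrying both the raw and
#' the canonical identifier so the reformatting is auditable. A record
#' counts as reformatted when its canonical MRN or canonical accession
#' differs from the raw export value.
#'
#' @param records data.frame of cohort records with columns `patient_id`,
#'   `accession`, `hospital` (raw identifiers as exported).
#' @param rules a [site_rules()] table. Sites absent from the table get
#'   identity rules.
#' @return A list with elements:
#'   \describe{
#'     \item{records}{the input with added columns `mrn_canonical`,
#'       `accession_canonical`, `reformatted` (logical).}
#'     \item{n_reformatted}{number of records whose MRN or ACC changed.}
#'     \item{non_numeric_mrn}{audit vector of raw MRNs containing
#'       non-digit characters (padded as-is).}
#'   }
#' @export
normalize_cohort <- function(records, rules) {
  assert_columns(records, c("patient_id", "accession", "hospital"),
                 "cohort records")
  dt <- as.data.table(records)
  rl <- as.data.table(rules)
  dt[, mrn_canonical := trimws(as.character(patient_id))]
  dt[, accession_canonical := trimws(as.character(accession))]
  for (i in seq_len(nrow(rl))) {
    site <- rl$hospital[i]
    idx <- which(dt$hospital == site)
    if (!length(idx)) next
    dt[idx, mrn_canonical := normalize_mrn(mrn_canonical,
                                           rl$mrn_pad_width[i])]
    dt[idx, accession_canonical := normalize_accession(
      accession_canonical, rl$acc_strip_prefix[i])]
  }
  dt[, reformatted := (mrn_canonical != trimws(as.character(patient_id))) |
       (accession_canonical != trimws(as.character(accession)))]
  non_numeric <- unique(dt$mrn_canonical[grepl("[^0-9]", dt$mrn_canonical)])
  list(records = dt[],
       n_reformatted = sum(dt$reformatted),
       non_numeric_mrn = non_numeric)
}
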