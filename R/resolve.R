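#' Normalize body-part strings against a controlled vocabulary
#'
#' PACS indices spell body parts inconsistently ("ABDOMEN", "Abd", "abd
#' pelvis"...). Resolution works on a small controlled vocabulary:
#' `abdomen`, `gi`, `gu`, `body`, `pelvis`, `chest`, or `other`. The
#' default map covers common site spellings; pass `vocab` to extend it.
#'
#' @param x character vector of raw body-part strings.
#' @param vocab named character vector mapping lowercased, trimmed site
#'   spellings to canonical tokens.
#' @return Character vector of canonical tokens.
#' @export
normalize_body_part <- function(x, vocab = default_body_part_vocab()) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(vocab[key])
  out[is.na(out)] <- "other"
  out
}

#' @rdname normalize_body_part
#' @export
default_body_part_vocab <- function() {
  c(abdomen = "abdomen", abd = "abdomen", abdo = "abdomen",
    gi = "gi", gu = "gu", body = "body",
    pelvis = "pelvis", pel = "pelvis",
    chest = "chest", thorax = "chest")
}

# Cascade preference rank of a canonical body part: abdomen-group studies
# first, then pelvis, then chest; anything else is never selectable.
body_part_rank <- function(bp_canonical) {
  rank <- rep(NA_integer_, length(bp_canonical))
  rank[bp_canonical %in% c("abdomen", "gi", "gu", "body")] <- 1L
  rank[bp_canonical == "pelvis"] <- 2L
  rank[bp_canonical == "chest"] <- 3L
  rank
}

#' Find candidate studies for one exam
#'
#' Queries a PACS study index with the patient's canonical MRN and exam
#' date. Candidates are CT studies for that MRN whose study date lies
#' within `window_days` of the exam date and which carry strictly more
#' than `min_images` images (the default, 20, drops billing-only
#' accessions and partial imports of outside scans).
#'
#' @param index PACS study index with columns `mrn`, `accession`,
#'   `study_date`, `body_part`, `modality`, `image_count`.
#' @param mrn canonical MRN (scalar).
#' @param exam_date exam date (`Date` or ISO-8601 string).
#' @param window_days non-negative integer date window.
#' @param min_images strict lower bound on image count.
#' @return The matching index rows with an added `abs_diff` column
#'   (absolute date difference in days). Empty result is valid.
#' @export
find_candidates <- function(index, mrn, exam_date, window_days = 0L,
                            min_images = 20L) {
  assert_columns(index, c("mrn", "accession", "study_date", "body_part",
                          "modality", "image_count"), "PACS index")
  dt <- as.data.table(index)
  d0 <- as_date_safe(exam_date)
  keep_row <- dt[["mrn"]] == mrn & dt[["modality"]] == "CT" &
    dt[["image_count"]] > min_images
  hit <- dt[which(keep_row)]
  if (!nrow(hit)) {
    hit[, abs_diff := integer(0)]
    return(hit[])
  }
  hit[, abs_diff := abs(as.integer(as_date_safe(study_date) - d0))]
  hit[abs_diff <= as.integer(window_days)]
}

#' Resolve the image-bearing accession for one exam
#'
#' Applies the selection cascade to the candidate sets returned by
#' [find_candidates()] at the exact-date window and at the expanded
#' window: (1) same-date candidates with body part abdomen/GI/GU/body;
#' (2) same-date pelvis, then same-date chest; (3) the same body-part
#' preference repeated over the expanded-window set. Within a tier, ties
#' break by smallest absolute date difference, then largest image count,
#' then lexicographic accession — so the choice is deterministic and
#' independent of candidate order.
#'
#' @param candidates_w0 candidates at window 0 (exact date).
#' @param candidates_w4 candidates at the expanded window (a superset of
#'   `candidates_w0` in normal use).
#' @param vocab body-part vocabulary for [normalize_body_part()].
#' @param expanded_window the window (days) the expanded set was built
#'   with; recorded in the result.
#' @return A one-row `data.frame`: `status` ("resolved"/"unresolved"),
#'   `chosen_accession`, `tier` (`abdomen_same_window`,
#'   `pelvis_or_chest_same_window`, or `date_expanded`), `window_used`,
#'   `date_diff`.
#' @export
resolve_accession <- function(candidates_w0, candidates_w4,
                              vocab = default_body_part_vocab(),
                              expanded_window = 4L) {
  w4 <- as.data.table(candidates_w4)
  w0 <- as.data.table(candidates_w0)
  pool <- unique(rbindlist(list(w0, w4), use.names = TRUE, fill = TRUE),
                 by = c("accession", "study_date"))
  unresolved <- data.frame(status = "unresolved",
                           chosen_accession = NA_character_,
                           tier = NA_character_,
                           window_used = NA_integer_,
                           date_diff = NA_integer_,
                           stringsAsFactors = FALSE)
  if (!nrow(pool)) return(unresolved)
  if (!"abs_diff" %in% names(pool)) {
    stop_validation("candidates must carry abs_diff (use find_candidates)",
                    "cohortforge_bad_candidates")
  }
  pool[, bp_rank := body_part_rank(normalize_body_part(body_part, vocab))]
  pool <- pool[!is.na(bp_rank)]
  if (!nrow(pool)) return(unresolved)
  # cascade order as a single lexicographic key: exact-date tiers strictly
  # precede every expanded-window tier
  pool[, priority := ifelse(abs_diff == 0L, 0L, 3L) + bp_rank]
  setorderv(pool, c("priority", "abs_diff", "image_count", "accession"),
            order = c(1L, 1L, -1L, 1L))
  top <- pool[1L]
  tier <- if (top$priority == 1L) "abdomen_same_window"
          else if (top$priority <= 3L) "pelvis_or_chest_same_window"
          else "date_expanded"
  data.frame(status = "resolved",
             chosen_accession = top$accession,
             tier = tier,
             window_used = if (top$priority <= 3L) 0L
                           else as.integer(expanded_window),
             date_diff = top$abs_diff,
             stringsAsFactors = FALSE)
}

#' Resolve every cohort exam against the PACS indices
#'
#' Vectorized driver: joins the cohort to the combined PACS index on
#' canonical MRN, applies the image-count and date-window filters, and
#' picks each exam's accession by the cascade of [resolve_accession()].
#'
#' @param cohort cohort records carrying `patient_id`,
#'   `accession_canonical`, `mrn_canonical`, `exam_date` (run
#'   [normalize_cohort()] first).
#' @param index combined PACS study index (all hospitals).
#' @param window_days expanded date window (days).
#' @param min_images strict image-count floor.
#' @param vocab body-part vocabulary.
#' @return A data.table, one row per cohort exam: exam key (`patient_id`,
#'   `registry_accession` = canonical registry accession), `status`,
#'   `chosen_accession`, `tier`, `window_used`, `date_diff`,
#'   `differs_from_registry`.
#' @export
resolve_cohort <- function(cohort, index, window_days = 4L,
                           min_images = 20L,
                           vocab = default_body_part_vocab()) {
  assert_columns(cohort, c("patient_id", "accession_canonical",
                           "mrn_canonical", "exam_date"), "cohort")
  assert_columns(index, c("mrn", "accession", "study_date", "body_part",
                          "modality", "image_count"), "PACS index")
  co <- as.data.table(cohort)[, .(
    patient_id, registry_accession = accession_canonical,
    mrn_canonical, exam_date = as_date_safe(exam_date))]
  co[, exam_id := .I]
  idx <- as.data.table(index)[modality == "CT" & image_count > min_images,
                              .(mrn, accession, study_date =
                                  as_date_safe(study_date),
                                body_part, image_count)]
  idx[, bp_rank := body_part_rank(normalize_body_part(body_part, vocab))]
  idx <- idx[!is.na(bp_rank)]

  cand <- idx[co, on = .(mrn = mrn_canonical), allow.cartesian = TRUE,
              nomatch = NULL,
              .(exam_id = i.exam_id,
                accession = x.accession,
                abs_diff = abs(as.integer(x.study_date - i.exam_date)),
                bp_rank = x.bp_rank,
                image_count = x.image_count)]
  cand <- cand[abs_diff <= as.integer(window_days)]
  res <- co[, .(exam_id, patient_id, registry_accession)]
  if (nrow(cand)) {
    cand[, priority := ifelse(abs_diff == 0L, 0L, 3L) + bp_rank]
    setorderv(cand, c("exam_id", "priority", "abs_diff", "image_count",
                      "accession"),
              order = c(1L, 1L, 1L, -1L, 1L))
    best <- cand[!duplicated(exam_id)]
    res <- best[res, on = "exam_id"]
  } else {
    res[, `:=`(accession = NA_character_, priority = NA_integer_,
               abs_diff = NA_integer_)]
  }
  res[, status := ifelse(is.na(accession), "unresolved", "resolved")]
  res[, chosen_accession := accession]
  res[, tier := fifelse(is.na(priority), NA_character_,
                 fifelse(priority == 1L, "abdomen_same_window",
                 fifelse(priority <= 3L, "pelvis_or_chest_same_window",
                         "date_expanded")))]
  res[, window_used := fifelse(is.na(priority), NA_integer_,
                        fifelse(priority <= 3L, 0L,
                                as.integer(window_days)))]
  res[, date_diff := abs_diff]
  res[, differs_from_registry :=
        status == "resolved" & chosen_accession != registry_accession]
  out <- res[, .(patient_id, registry_accession, status, chosen_accession,
                 tier, window_used, date_diff, differs_from_registry)]
  setorderv(out, c("patient_id", "registry_accession"))
  out[]
}

#' Flag exams resolved to a non-registry accession
#'
#' Counts and lists the resolved exams whose chosen accession differs from
#' the canonical accession the registry provided, on canonical form.
#'
#' @param results output of [resolve_cohort()].
#' @return A list with `n` and `flagged` (sorted by exam key).
#' @export
flag_registry_discrepancies <- function(results) {
  assert_columns(results, c("patient_id", "registry_accession", "status",
                            "chosen_accession"), "resolution results")
  dt <- as.data.table(results)
  flagged <- dt[status == "resolved" &
                  chosen_accession != registry_accession]
  setorderv(flagged, c("patient_id", "registry_accession"))
  list(n = nrow(flagged), flagged = flagged[])
}

#' Score resolutions against fixture ground truth
#'
#' For synthetic fixtures the generator records, per exam, which accession
#' actually carries the images. This compares every resolved exam against
#' that truth and returns the disagreements as an override table, enabling
#' replay of the manual corrections a curation team would apply.
#'
#' @param results output of [resolve_cohort()].
#' @param ground_truth fixture ground truth with `patient_id`,
#'   `registry_accession`, `true_accession`.
#' @return A list with `n` (count of resolved exams whose chosen accession
#'   is not the image-bearing one) and `overrides` (exam key, chosen,
#'   `true_accession`).
#' @export
flag_misresolutions <- function(results, ground_truth) {
  if (is.null(ground_truth)) {
    stop_validation("ground truth is required to score mis-resolutions",
                    "cohortforge_missing_ground_truth")
  }
  assert_columns(ground_truth, c("patient_id", "registry_accession",
                                 "true_accession"), "ground truth")
  dt <- as.data.table(results)
  gt <- as.data.table(ground_truth)
  dt <- gt[, .(patient_id, registry_accession, true_accession)][
    dt, on = c("patient_id", "registry_accession")]
  bad <- dt[status == "resolved" & !is.na(true_accession) &
              chosen_accession != true_accession]
  setorderv(bad, c("patient_id", "registry_accession"))
  list(n = nrow(bad),
       overrides = bad[, .(patient_id, registry_accession,
                           chosen_accession, true_accession)])
}

#' Apply manual-correction overrides to resolution results
#'
#' Replays curation-team corrections: for every exam in the override
#' table, the chosen accession is replaced by the verified image-bearing
#' accession.
#'
#' @param results output of [resolve_cohort()].
#' @param overrides `overrides` element of [flag_misresolutions()].
#' @return Corrected results (same shape as `results`).
#' @export
apply_resolution_overrides <- function(results, overrides) {
  dt <- copy(as.data.table(results))
  if (is.null(overrides) || !nrow(overrides)) return(dt[])
  ov <- as.data.table(overrides)
  dt[ov, on = c("patient_id", "registry_accession"),
     chosen_accession := i.true_accession]
  dt[, differs_from_registry :=
       status == "resolved" & chosen_accession != registry_accession]
  dt[]
}
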