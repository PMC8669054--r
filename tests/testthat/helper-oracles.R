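# Independent oracles, written as literal transcriptions of the documented
# rules so they share no code with the implementation they check.

# Brute-force resolver: walk the cascade tiers in order and pick the best
# candidate by explicit loops.
oracle_resolve <- function(candidates) {
  if (!nrow(candidates)) return(NA_character_)
  grp <- function(bp) {
    bp <- tolower(trimws(bp))
    if (bp %in% c("abdomen", "abd", "abdo", "gi", "gu", "body")) "abd"
    else if (bp %in% c("pelvis", "pel")) "pelvis"
    else if (bp %in% c("chest", "thorax")) "chest"
    else "other"
  }
  tiers <- list(c(0, "abd"), c(0, "pelvis"), c(0, "chest"),
                c(4, "abd"), c(4, "pelvis"), c(4, "chest"))
  for (tier in tiers) {
    w <- as.integer(tier[1]); want <- tier[2]
    pool <- list()
    for (i in seq_len(nrow(candidates))) {
      row <- candidates[i, ]
      if (row$abs_diff <= w && grp(row$body_part) == want) {
        pool[[length(pool) + 1L]] <- row
      }
    }
    if (length(pool)) {
      best <- pool[[1]]
      for (row in pool[-1]) {
        better <- FALSE
        if (row$abs_diff < best$abs_diff) better <- TRUE
        else if (row$abs_diff == best$abs_diff) {
          if (row$image_count > best$image_count) better <- TRUE
          else if (row$image_count == best$image_count &&
                   row$accession < best$accession) better <- TRUE
        }
        if (better) best <- row
      }
      return(best$accession)
    }
  }
  NA_character_
}

# Random candidate set from the small universe used by the resolver
# property tests: body parts x date offsets x image counts.
random_candidates <- function(size) {
  universe <- expand.grid(
    body_part = c("ABDOMEN", "PELVIS", "CHEST"),
    diff = c(0L, -1L, 1L, -3L, 3L, -4L, 4L),
    image_count = c(21L, 50L),
    stringsAsFactors = FALSE)
  pick <- universe[sample.int(nrow(universe), size), , drop = FALSE]
  data.frame(
    mrn = "00000001",
    accession = sprintf("9%08d", sample.int(99999999L, size)),
    study_date = as.character(as.Date("2012-06-15") + pick$diff),
    body_part = pick$body_part,
    modality = "CT",
    image_count = pick$image_count,
    abs_diff = abs(pick$diff),
    stringsAsFactors = FALSE)
}

# Discrete-event transfer oracle in study granularity: studies are pushed
# one at a time at 1/push intervals and written at 1/write intervals from
# a FIFO buffer. Times are active hours.
oracle_transfer <- function(push, write, capacity, volume) {
  t_push <- (seq_len(volume)) / push           # arrival of study k
  buffer <- 0L
  writer_free <- 0
  peak <- 0L
  done <- 0
  arrivals <- t_push
  i <- 1L                                      # next arrival
  pending <- 0L                                # studies in buffer
  written <- 0L
  t <- 0
  while (written < volume) {
    next_arrival <- if (i <= volume) arrivals[i] else Inf
    next_write <- if (pending > 0L && write > 0) writer_free + 1 / write
                  else Inf
    if (next_arrival <= next_write) {
      t <- next_arrival
      pending <- pending + 1L
      i <- i + 1L
      if (pending > capacity) {
        return(list(overflowed = TRUE, time = t, peak = pending))
      }
      peak <- max(peak, pending)
      # the writer was idle iff the buffer was empty before this arrival
      if (pending == 1L && writer_free < t) writer_free <- t
    } else if (is.finite(next_write)) {
      t <- next_write
      writer_free <- t
      pending <- pending - 1L
      written <- written + 1L
    } else {
      return(list(overflowed = FALSE, time = NA_real_, peak = peak,
                  stalled = TRUE))
    }
  }
  list(overflowed = FALSE, time = t, peak = peak, stalled = FALSE)
}

# Row-by-row predicate oracle for the registry filters.
oracle_keep <- function(row, config) {
  row$modality %in% config$modality &&
    as.integer(format(as.Date(row$exam_date), "%Y")) %in% config$year &&
    grepl(tolower(config$description_substring),
          tolower(row$exam_description), fixed = TRUE) &&
    !(tolower(row$exam_group) %in% config$excluded_groups) &&
    !(tolower(row$patient_type) %in% config$excluded_patient_types) &&
    row$age >= config$age_range[1] && row$age <= config$age_range[2]
}
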