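#' Describe a bulk-transfer scenario
#'
#' Bulk retrieval stages studies through an intermediate archive: a
#' producer pushes studies into a finite buffer at `push_rate` while a
#' consumer drains them to research storage at `write_rate`. When the push
#' rate exceeds the write rate the buffer fills and, once capacity is
#' exceeded, the staging service crashes — the classic failure of
#' unthrottled archive-to-storage transfer. Remediation is slowing the
#' push and/or enlarging the buffer.
#'
#' Rates are in studies per *active* hour. If `nightly_window` is set (a
#' retrieval window of that many hours per day, e.g. transfers restricted
#' to nights to protect clinical PACS load), reported times are wall-clock
#' hours under that duty cycle; otherwise active time equals wall clock.
#'
#' @param push_rate studies/hour pushed into the buffer.
#' @param write_rate studies/hour written out of the buffer.
#' @param buffer_capacity buffer size in studies.
#' @param total_volume total studies to transfer (> 0).
#' @param nightly_window optional active hours per 24-hour day.
#' @return A list of class `transfer_scenario`.
#' @export
transfer_scenario <- function(push_rate, write_rate, buffer_capacity,
                              total_volume, nightly_window = NULL) {
  vals <- c(push_rate, write_rate, buffer_capacity, total_volume)
  if (anyNA(vals) || any(vals < 0)) {
    stop_validation("transfer scenario values must be non-negative",
                    "cohortforge_bad_scenario")
  }
  if (total_volume <= 0 || push_rate <= 0) {
    stop_validation("total_volume and push_rate must be positive",
                    "cohortforge_bad_scenario")
  }
  if (!is.null(nightly_window) &&
      (nightly_window <= 0 || nightly_window > 24)) {
    stop_validation("nightly_window must be in (0, 24]",
                    "cohortforge_bad_scenario")
  }
  structure(list(push_rate = push_rate, write_rate = write_rate,
                 buffer_capacity = buffer_capacity,
                 total_volume = total_volume,
                 nightly_window = nightly_window),
            class = "transfer_scenario")
}

#' Simulate a bulk transfer (fluid model)
#'
#' Closed-form fluid approximation of the producer-consumer buffer. While
#' the producer is active the buffer level grows at `push - write` (never
#' below zero); the transfer overflows when the level exceeds capacity, at
#' active time `capacity / (push - write)`; otherwise it completes when
#' the last study is written, at `volume / min(push, write)` active hours.
#' A zero write rate with volume within capacity neither overflows nor
#' completes and is reported as stalled.
#'
#' @param scenario a [transfer_scenario()].
#' @return A list of class `transfer_outcome`: `status` (`"completed"`,
#'   `"overflowed"`, or `"stalled"`), `overflowed`, `time_to_overflow`
#'   (wall-clock hours, or `NA`), `completion_time` (wall-clock hours, or
#'   `NA`), `peak_buffer` (studies), `duty_cycle`.
#' @export
simulate_transfer <- function(scenario) {
  stopifnot(inherits(scenario, "transfer_scenario"))
  p <- scenario$push_rate
  w <- scenario$write_rate
  cap <- scenario$buffer_capacity
  vol <- scenario$total_volume
  duty <- if (is.null(scenario$nightly_window)) 1
          else scenario$nightly_window / 24
  wall <- function(active_hours) active_hours / duty

  if (p > w) {
    produce_time <- vol / p               # active hours of pushing
    peak <- (p - w) * produce_time        # level when the producer stops
    if (peak > cap) {
      t_over <- cap / (p - w)
      if (t_over <= produce_time) {
        return(structure(list(status = "overflowed", overflowed = TRUE,
                              time_to_overflow = wall(t_over),
                              completion_time = NA_real_,
                              peak_buffer = cap,
                              duty_cycle = duty),
                         class = "transfer_outcome"))
      }
    }
    if (w == 0) {
      # everything fits in the buffer but can never drain
      return(structure(list(status = "stalled", overflowed = FALSE,
                            time_to_overflow = NA_real_,
                            completion_time = NA_real_,
                            peak_buffer = min(peak, cap),
                            duty_cycle = duty),
                       class = "transfer_outcome"))
    }
    return(structure(list(status = "completed", overflowed = FALSE,
                          time_to_overflow = NA_real_,
                          completion_time = wall(vol / w),
                          peak_buffer = peak,
                          duty_cycle = duty),
                     class = "transfer_outcome"))
  }
  # write keeps pace with push: buffer stays at fluid level zero
  structure(list(status = "completed", overflowed = FALSE,
                 time_to_overflow = NA_real_,
                 completion_time = wall(vol / p),
                 peak_buffer = 0,
                 duty_cycle = duty),
            class = "transfer_outcome")
}

#' @export
print.transfer_outcome <- function(x, ...) {
  cat("Bulk transfer outcome:", x$status, "\n")
  if (x$status == "overflowed") {
    cat(sprintf("  buffer overflow after %.2f wall-clock hours\n",
                x$time_to_overflow))
  } else if (x$status == "completed") {
    cat(sprintf("  completed in %.2f wall-clock hours (peak buffer %.0f studies)\n",
                x$completion_time, x$peak_buffer))
  } else {
    cat("  transfer stalls: nothing is ever written to storage\n")
  }
  invisible(x)
}
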