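# Summary computed from a finalized, sorted event list. `duration_ms` is the
# actual session length (the session_end offset), which is what tic rates
# are normalized by; it equals the planned duration unless the session was
# ended early.
compute_summary <- function(events, undelivered_reward_count = 0L) {
  tics <- sort(events$offset[events$kind == "tic"])
  rewards <- events$offset[events$kind == "reward"]
  end_off <- events$offset[events$kind == "session_end"]
  if (length(end_off) != 1L) {
    tsp_state_error("events must contain exactly one session_end")
  }
  duration <- end_off
  structure(
    list(tic_count = length(tics),
         reward_count = length(rewards),
         undelivered_reward_count = as.integer(undelivered_reward_count),
         duration_ms = duration,
         tics_per_minute = length(tics) / (duration / 60000),
         mean_inter_tic_interval_ms =
           if (length(tics) >= 2) mean(diff(tics)) else NA_real_,
         longest_tic_free_interval_ms = max(diff(c(0, tics, duration)))),
    class = "tsp_summary")
}

#' Summarize a session record
#'
#' Recomputes the per-session summary from the event list: tic and reward
#' counts, tic rate per minute, mean inter-tic interval (defined only with
#' two or more tics) and the longest tic-free interval. Tic-free intervals
#' are the gaps between consecutive tics plus the two boundary gaps (session
#' start to first tic, last tic to session end); with zero tics the longest
#' tic-free interval is the whole session. The NCR `undelivered_reward_count`
#' (source rewards scheduled beyond the session's end) is taken from the
#' record, since an archived log references its source schedule by filename
#' only.
#'
#' @param record A `tsp_record`.
#' @return A `tsp_summary` list.
#' @export
summarize_session <- function(record) {
  if (!inherits(record, "tsp_record")) tsp_state_error("not a tsp_record")
  compute_summary(record$events,
                  record$summary$undelivered_reward_count %||% 0L)
}

#' @export
print.tsp_summary <- function(x, ...) {
  cat(sprintf(
    "  tics: %d (%.3g/min)  rewards: %d delivered, %d undelivered\n",
    x$tic_count, x$tics_per_minute, x$reward_count,
    x$undelivered_reward_count))
  cat(sprintf("  longest tic-free interval: %g ms",
              x$longest_tic_free_interval_ms))
  if (!is.na(x$mean_inter_tic_interval_ms)) {
    cat(sprintf("  mean inter-tic interval: %g ms",
                x$mean_inter_tic_interval_ms))
  }
  cat("\n")
  invisible(x)
}

#' Suppression ratio between two sessions
#'
#' Tic rate in the reinforced (or otherwise manipulated) session divided by
#' the tic rate at baseline; values below 1 indicate suppression. Undefined
#' (returned as `NA`) when the baseline rate is zero.
#'
#' @param x,baseline `tsp_summary` or `tsp_record` objects.
#' @return A non-negative number, or `NA_real_` if not computable.
#' @export
#' @examples
#' suppression_ratio(
#'   list(tics_per_minute = 1), list(tics_per_minute = 4))
suppression_ratio <- function(x, baseline) {
  as_summary <- function(s) {
    if (inherits(s, "tsp_record")) s <- s$summary
    s
  }
  x <- as_summary(x); baseline <- as_summary(baseline)
  if (!is_scalar_number(baseline$tics_per_minute) ||
      baseline$tics_per_minute == 0) {
    return(NA_real_)
  }
  x$tics_per_minute / baseline$tics_per_minute
}

#' Tabulate summaries across sessions
#'
#' One row per session record, suitable for TSV export and cross-condition
#' analysis.
#'
#' @param records A list of `tsp_record` objects.
#' @return A data frame with one row per record.
#' @export
summary_table <- function(records) {
  if (inherits(records, "tsp_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    s <- r$summary
    data.frame(research_id = r$research_id,
               condition = r$condition,
               start_datetime = r$start_datetime,
               duration_ms = s$duration_ms,
               tic_count = s$tic_count,
               reward_count = s$reward_count,
               undelivered_reward_count = s$undelivered_reward_count,
               tics_per_minute = s$tics_per_minute,
               mean_inter_tic_interval_ms = s$mean_inter_tic_interval_ms,
               longest_tic_free_interval_ms = s$longest_tic_free_interval_ms,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
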