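TSP_CONDITIONS <- c("baseline", "verbal", "DRZ", "NCR")
REWARDED_CONDITIONS <- c("DRZ", "NCR")
END_REASONS <- c("duration elapsed", "rater ended", "connection closed")

# Event ordering at equal offsets: a tic sorts before a reward, so a tic
# landing exactly on a DRO due time pre-empts the reward.
KIND_PRIORITY <- c(session_start = 0L, tic = 1L, reward = 2L, session_end = 3L)

#' Session configuration
#'
#' Builds and validates the configuration of one TSP session. Times are
#' integer milliseconds from session start throughout the package; the only
#' wall-clock value is the start datetime recorded by [start_session()].
#'
#' @param condition One of `"baseline"`, `"verbal"`, `"DRZ"` (the DRO
#'   condition) or `"NCR"`.
#' @param planned_duration_ms Planned session length in milliseconds (> 0).
#' @param research_id Subject research ID; a non-empty token without
#'   underscores, path separators or whitespace (it becomes the first field
#'   of the archive filename).
#' @param dro_interval_ms Length of the tic-free interval rewarded under
#'   `DRZ`, in milliseconds. Default 10000 (a reward after every 10 s
#'   without a tic).
#' @param ncr_source For `NCR` only: the reward schedule to replay, either a
#'   [reward_schedule()] or a finalized session record (from which the
#'   schedule is extracted). Must carry the same `research_id` (NCR replays
#'   a log previously created with the current subject).
#' @return An object of class `tsp_config`.
#' @export
#' @examples
#' session_config("DRZ", 300000, "au5")
session_config <- function(condition, planned_duration_ms, research_id,
                           dro_interval_ms = 10000, ncr_source = NULL) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% TSP_CONDITIONS) {
    tsp_config_error(sprintf("condition must be one of %s",
                             paste(TSP_CONDITIONS, collapse = ", ")))
  }
  if (!is_scalar_number(planned_duration_ms) || planned_duration_ms <= 0) {
    tsp_config_error("planned_duration_ms must be a positive number")
  }
  if (!is_scalar_number(dro_interval_ms) || dro_interval_ms <= 0) {
    tsp_config_error("dro_interval_ms must be a positive number")
  }
  check_research_id(research_id)
  if (condition == "NCR") {
    if (is.null(ncr_source)) {
      tsp_config_error("ncr_source is required for the NCR condition")
    }
    sched <- if (inherits(ncr_source, "tsp_record")) {
      extract_reward_schedule(ncr_source)
    } else if (inherits(ncr_source, "reward_schedule")) {
      ncr_source
    } else {
      tsp_config_error(
        "ncr_source must be a reward_schedule or a tsp_record")
    }
    if (!identical(sched$source_research_id, research_id)) {
      tsp_config_error(sprintf(
        "ncr_source subject '%s' does not match research_id '%s': NCR must replay a log previously created with the current subject",
        sched$source_research_id, research_id))
    }
    ncr_source <- sched
  } else if (!is.null(ncr_source)) {
    tsp_config_error("ncr_source is only allowed for the NCR condition")
  }
  structure(
    list(condition = condition,
         planned_duration_ms = as.numeric(planned_duration_ms),
         dro_interval_ms = as.numeric(dro_interval_ms),
         research_id = research_id,
         ncr_source = ncr_source),
    class = "tsp_config")
}

#' @export
print.tsp_config <- function(x, ...) {
  cat(sprintf("TSP session config: %s, %g ms planned, subject %s\n",
              x$condition, x$planned_duration_ms, x$research_id))
  if (x$condition == "DRZ") {
    cat(sprintf("  DRO interval: %g ms\n", x$dro_interval_ms))
  }
  if (x$condition == "NCR") {
    cat(sprintf("  NCR source: %s (%d rewards)\n",
                x$ncr_source$source_filename, length(x$ncr_source$offsets)))
  }
  invisible(x)
}

new_event_frame <- function() {
  data.frame(offset = 0, kind = "session_start", detail = "",
             stringsAsFactors = FALSE)
}

append_event <- function(state, offset, kind, detail = "") {
  state$events <- rbind(
    state$events,
    data.frame(offset = offset, kind = kind, detail = detail,
               stringsAsFactors = FALSE))
  # last_reset anchors the DRO countdown: start of session, last tic or
  # last reward, whichever is latest.
  if (kind %in% c("tic", "reward")) {
    state$last_reset <- max(state$last_reset, offset)
  }
  state
}

#' Start a session
#'
#' Creates a live session state with a single `session_start` event at
#' offset 0.
#'
#' @param config A [session_config()].
#' @param start_datetime Wall-clock session start, recorded once for the
#'   archive filename and log header; a `POSIXct` or a
#'   `"YYYY-MM-DD HH:MM:SS"` string. Defaults to the current time.
#' @return An object of class `tsp_state`.
#' @export
start_session <- function(config, start_datetime = Sys.time()) {
  if (!inherits(config, "tsp_config")) {
    tsp_config_error("config must be a tsp_config")
  }
  structure(
    list(config = config,
         start_datetime = canonical_datetime(start_datetime),
         elapsed = 0,
         last_reset = 0,
         ncr_next = 1L,
         events = new_event_frame(),
         live = TRUE),
    class = "tsp_state")
}

# Emit every reward whose due time falls within the emission window ending
# at `horizon`. DRZ due times recur at last_reset + dro_interval, the
# countdown restarting at each emission; NCR due times are the source
# schedule offsets, consumed in order via a cursor.
emit_due <- function(state, horizon, include_equal = TRUE) {
  cfg <- state$config
  if (cfg$condition == "DRZ") {
    repeat {
      due <- state$last_reset + cfg$dro_interval_ms
      hit <- if (include_equal) due <= horizon else due < horizon
      if (!hit) break
      state <- append_event(state, due, "reward")
    }
  } else if (cfg$condition == "NCR") {
    offs <- cfg$ncr_source$offsets
    while (state$ncr_next <= length(offs)) {
      o <- offs[state$ncr_next]
      hit <- if (include_equal) o <= horizon else o < horizon
      if (!hit) break
      state <- append_event(state, o, "reward")
      state$ncr_next <- state$ncr_next + 1L
    }
  }
  state
}

check_live <- function(state, what) {
  if (!inherits(state, "tsp_state")) tsp_state_error("not a tsp_state")
  if (!state$live) tsp_state_error(paste(what, "on an ended session"))
  invisible(state)
}

#' Record an observed tic
#'
#' Appends a tic event at `now`. Under `DRZ` the tic-free countdown restarts
#' at the tic; rewards that fell due strictly before the tic are emitted
#' first, and a reward due exactly at the tic offset is pre-empted (never
#' reward an interval containing a tic). Under `NCR` the replay schedule is
#' unaffected by tics: a source reward at the tic offset is still delivered,
#' ordered after the tic.
#'
#' @param state A live `tsp_state`.
#' @param now Tic offset in milliseconds; must be `>= state$elapsed` and
#'   strictly before the planned duration.
#' @return The updated `tsp_state`.
#' @export
record_tic <- function(state, now) {
  check_live(state, "tic recorded")
  if (!is_scalar_number(now) || now < state$elapsed) {
    tsp_state_error("tic offset must be >= the session's elapsed time")
  }
  if (now >= state$config$planned_duration_ms) {
    tsp_state_error("tic recorded after the planned session duration")
  }
  state <- emit_due(state, now,
                    include_equal = state$config$condition == "NCR")
  state <- append_event(state, now, "tic")
  state$elapsed <- now
  state
}

#' Next reward due time
#'
#' The offset at which the next reward falls due, or `NULL` when no reward
#' is pending: under `DRZ` this is `last_reset + dro_interval_ms`; under
#' `NCR`, the smallest unconsumed source offset (none once the schedule is
#' exhausted or extends beyond the planned duration); under `baseline` and
#' `verbal`, always `NULL`. Pure: does not mutate the state.
#'
#' @param state A live `tsp_state`.
#' @return Due offset in milliseconds, or `NULL`.
#' @export
next_reward_due <- function(state) {
  check_live(state, "reward query")
  cfg <- state$config
  switch(cfg$condition,
         DRZ = state$last_reset + cfg$dro_interval_ms,
         NCR = {
           offs <- cfg$ncr_source$offsets
           if (state$ncr_next > length(offs)) return(NULL)
           o <- offs[state$ncr_next]
           if (o > cfg$planned_duration_ms) NULL else o
         },
         NULL)
}

#' Advance the session clock
#'
#' Drives the engine forward to `now`, emitting every reward whose due time
#' lies in `(elapsed, min(now, planned_duration)]` in order (each emission
#' restarting the DRO countdown). If `now` reaches the planned duration a
#' `session_end` event with detail `"duration elapsed"` is appended at the
#' planned duration and the state goes dead.
#'
#' @param state A live `tsp_state`.
#' @param now Target offset in milliseconds, `>= state$elapsed`.
#' @return A list with elements `state` (updated `tsp_state`) and `emitted`
#'   (data frame of the events emitted by this call).
#' @export
advance_session <- function(state, now) {
  check_live(state, "advance")
  if (!is_scalar_number(now) || now < state$elapsed) {
    tsp_state_error("cannot advance the session clock backwards")
  }
  dur <- state$config$planned_duration_ms
  horizon <- min(now, dur)
  n0 <- nrow(state$events)
  state <- emit_due(state, horizon, include_equal = TRUE)
  if (now >= dur) {
    state <- append_event(state, dur, "session_end", "duration elapsed")
    state$live <- FALSE
  }
  state$elapsed <- horizon
  emitted <- state$events[seq_len(nrow(state$events)) > n0, , drop = FALSE]
  rownames(emitted) <- NULL
  list(state = state, emitted = emitted)
}

#' End a session
#'
#' Ends the session at `min(now, planned_duration)` for the given reason,
#' emitting any rewards that fell due up to that point, and returns the
#' finalized, summarized session record. The reason vocabulary is fixed so
#' logs stay machine-parseable.
#'
#' @param state A live `tsp_state`.
#' @param now End offset in milliseconds (clamped to the planned duration).
#' @param reason One of `"duration elapsed"`, `"rater ended"`,
#'   `"connection closed"`.
#' @return A `tsp_record` (see [finalize_record()]).
#' @export
end_session <- function(state, now, reason = "rater ended") {
  check_live(state, "end requested")
  if (!is.character(reason) || length(reason) != 1L ||
      !reason %in% END_REASONS) {
    tsp_config_error(sprintf("end reason must be one of: %s",
                             paste(END_REASONS, collapse = ", ")))
  }
  if (!is_scalar_number(now) || now < state$elapsed) {
    tsp_state_error("end offset must be >= the session's elapsed time")
  }
  eff <- min(now, state$config$planned_duration_ms)
  state <- emit_due(state, eff, include_equal = TRUE)
  state <- append_event(state, eff, "session_end", reason)
  state$live <- FALSE
  state$elapsed <- eff
  finalize_record(state)
}

#' Finalize a dead session state into an archivable record
#'
#' Sorts events by `(offset, kind priority)` (tic before reward at equal
#' offsets), computes the session summary and returns the immutable unit of
#' archival, a `tsp_record`.
#'
#' @param state A `tsp_state` whose session has ended (via [end_session()]
#'   or [advance_session()] past the planned duration).
#' @return An object of class `tsp_record` with fields `research_id`,
#'   `start_datetime`, `condition`, `planned_duration_ms`,
#'   `dro_interval_ms`, `ncr_source_file`, `events` and `summary`.
#' @export
finalize_record <- function(state) {
  if (!inherits(state, "tsp_state")) tsp_state_error("not a tsp_state")
  if (state$live) {
    tsp_state_error("cannot finalize a live session; end it first")
  }
  cfg <- state$config
  ev <- state$events
  ev <- ev[order(ev$offset, KIND_PRIORITY[ev$kind]), , drop = FALSE]
  rownames(ev) <- NULL
  rec <- structure(
    list(research_id = cfg$research_id,
         start_datetime = state$start_datetime,
         condition = cfg$condition,
         planned_duration_ms = cfg$planned_duration_ms,
         dro_interval_ms = cfg$dro_interval_ms,
         ncr_source_file = if (cfg$condition == "NCR")
           cfg$ncr_source$source_filename else NA_character_,
         events = ev,
         summary = NULL),
    class = "tsp_record")
  undelivered <- if (cfg$condition == "NCR") {
    length(cfg$ncr_source$offsets) - sum(ev$kind == "reward")
  } else 0L
  rec$summary <- compute_summary(ev, undelivered)
  rec
}

#' @export
print.tsp_record <- function(x, ...) {
  cat(sprintf("TSP session record: %s, subject %s, started %s\n",
              x$condition, x$research_id, x$start_datetime))
  cat(sprintf("  %d events over %g ms\n", nrow(x$events),
              x$summary$duration_ms))
  print(x$summary)
  invisible(x)
}

#' Run a complete session against a prepared tic stream
#'
#' Convenience driver used by simulations and the CLI: starts a session,
#' feeds each tic offset through [record_tic()] (rewards falling due between
#' tics are emitted as the clock passes them), advances to the planned
#' duration and finalizes. Tic offsets at or beyond the planned duration are
#' dropped (the session is already over when they occur).
#'
#' @param config A [session_config()].
#' @param tic_offsets Sorted (or sortable) numeric tic offsets in ms.
#' @param start_datetime Passed to [start_session()].
#' @return A `tsp_record`.
#' @export
#' @examples
#' cfg <- session_config("DRZ", 60000, "demo")
#' rec <- run_session(cfg, tic_offsets = c(3000, 7000))
#' rec$summary$reward_count
run_session <- function(config, tic_offsets = numeric(0),
                        start_datetime = Sys.time()) {
  state <- start_session(config, start_datetime)
  tics <- sort(tic_offsets)
  tics <- tics[tics >= 0 & tics < config$planned_duration_ms]
  for (t in tics) state <- record_tic(state, t)
  state <- advance_session(state, config$planned_duration_ms)$state
  finalize_record(state)
}
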