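#' Reward schedule for noncontingent replay
#'
#' A strictly increasing list of reward offsets (ms from session start),
#' carrying the identity of the archived session it came from. NCR sessions
#' deliver rewards at exactly these offsets, irrespective of tics.
#'
#' @param offsets Strictly increasing numeric offsets in ms (may be empty).
#' @param source_research_id Research ID of the subject the source session
#'   was recorded with.
#' @param source_filename Archive filename of the source log (recorded in
#'   the NCR log header).
#' @return An object of class `reward_schedule`.
#' @export
reward_schedule <- function(offsets, source_research_id,
                            source_filename = NA_character_) {
  offsets <- as.numeric(offsets)
  if (length(offsets)) {
    if (any(!is.finite(offsets)) || any(offsets <= 0)) {
      tsp_config_error("reward offsets must be positive and finite")
    }
    if (any(diff(offsets) <= 0)) {
      tsp_config_error("reward offsets must be strictly increasing")
    }
  }
  check_research_id(source_research_id)
  structure(
    list(offsets = offsets,
         source_research_id = source_research_id,
         source_filename = source_filename),
    class = "reward_schedule")
}

#' Extract the reward schedule from an archived session
#'
#' Projects the reward-event offsets out of a parsed or finalized record,
#' for replay in an NCR session. Replaying a log that is itself an NCR log
#' is permitted (offsets are offsets) but warned about.
#'
#' @param record A `tsp_record`.
#' @return A [reward_schedule()].
#' @export
extract_reward_schedule <- function(record) {
  if (!inherits(record, "tsp_record")) tsp_state_error("not a tsp_record")
  if (record$condition == "NCR") {
    warning("replaying a session that is itself an NCR replay",
            call. = FALSE)
  }
  reward_schedule(
    offsets = record$events$offset[record$events$kind == "reward"],
    source_research_id = record$research_id,
    source_filename = archive_filename(record$research_id,
                                       record$start_datetime,
                                       record$condition))
}

#' Build an NCR session configuration from a reward schedule
#'
#' The resulting configuration makes the engine emit rewards exactly at the
#' schedule offsets that fall within the session duration, regardless of
#' tics. Schedule offsets beyond the duration are dropped silently and
#' counted in the summary as undelivered. The schedule must come from a log
#' previously created with the current subject: a research-ID mismatch is a
#' configuration error.
#'
#' @param schedule A [reward_schedule()].
#' @param duration_ms Planned NCR session duration in ms.
#' @param research_id Research ID of the current subject.
#' @param dro_interval_ms Carried in the config header for completeness;
#'   unused by the NCR engine.
#' @return A [session_config()] with `condition = "NCR"`.
#' @export
make_ncr_config <- function(schedule, duration_ms, research_id,
                            dro_interval_ms = 10000) {
  if (!inherits(schedule, "reward_schedule")) {
    tsp_config_error("schedule must be a reward_schedule")
  }
  session_config("NCR", duration_ms, research_id,
                 dro_interval_ms = dro_interval_ms, ncr_source = schedule)
}
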