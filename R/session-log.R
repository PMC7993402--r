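# The .ttsd on-disk dialect implemented here, named in every file header so
# the format can evolve without breaking old archives.
TTSD_DIALECT <- "ttw-spec-1"
SUMMARY_SENTINEL <- "=== summary ==="

SUMMARY_FIELDS <- c("tic_count", "reward_count", "undelivered_reward_count",
                    "duration_ms", "tics_per_minute",
                    "mean_inter_tic_interval_ms",
                    "longest_tic_free_interval_ms")

canonical_datetime <- function(x) {
  if (inherits(x, "POSIXt")) return(format(x, "%Y-%m-%d %H:%M:%S"))
  if (is.character(x) && length(x) == 1L &&
      grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}:\\d{2}$", x)) {
    return(x)
  }
  tsp_config_error(
    "start_datetime must be a POSIXct or a 'YYYY-MM-DD HH:MM:SS' string")
}

#' Archive filename for a session
#'
#' Builds the archival filename
#' `<research_id>_<YYYYMMDD-HHMMSS>_<condition>.ttsd`. Because the research
#' ID may not contain underscores, the mapping is injective and the name can
#' be parsed back with [parse_archive_filename()].
#'
#' @param research_id Subject research ID (no underscores, path separators
#'   or whitespace).
#' @param start_datetime Session start, a `POSIXct` or
#'   `"YYYY-MM-DD HH:MM:SS"` string; second precision.
#' @param condition One of the four condition codes.
#' @return The filename as a string.
#' @export
#' @examples
#' archive_filename("au5", "2020-06-22 15:30:43", "baseline")
archive_filename <- function(research_id, start_datetime, condition) {
  check_research_id(research_id)
  if (!condition %in% TSP_CONDITIONS) {
    tsp_config_error("unknown condition code")
  }
  dt <- canonical_datetime(start_datetime)
  stamp <- paste0(gsub("-", "", substr(dt, 1, 10)), "-",
                  gsub(":", "", substr(dt, 12, 19)))
  sprintf("%s_%s_%s.ttsd", research_id, stamp, condition)
}

#' Parse an archive filename back into its fields
#'
#' @param filename A filename produced by [archive_filename()] (any leading
#'   directory part is ignored).
#' @return A list with `research_id`, `start_datetime`
#'   (`"YYYY-MM-DD HH:MM:SS"`) and `condition`.
#' @export
parse_archive_filename <- function(filename) {
  fn <- basename(filename)
  m <- regmatches(fn, regexec(
    "^([^_/\\\\[:space:]]+)_(\\d{8})-(\\d{6})_(baseline|verbal|DRZ|NCR)\\.ttsd$",
    fn))[[1]]
  if (length(m) != 5L) {
    tsp_config_error(sprintf("not a valid .ttsd archive filename: %s", fn))
  }
  d <- m[3]; t <- m[4]
  list(research_id = m[2],
       start_datetime = sprintf("%s-%s-%s %s:%s:%s",
                                substr(d, 1, 4), substr(d, 5, 6),
                                substr(d, 7, 8), substr(t, 1, 2),
                                substr(t, 3, 4), substr(t, 5, 6)),
       condition = m[5])
}

#' Serialize a session record to .ttsd text
#'
#' Produces the line-oriented plain-text form of a finalized record:
#' `key: value` header lines (dialect, research ID, condition, start
#' datetime, planned duration, DRO interval, NCR source filename if any),
#' one tab-separated line per event (`offset<TAB>kind<TAB>detail`), then a
#' summary block introduced by the sentinel line `=== summary ===`. Output
#' bytes are deterministic for a given record.
#'
#' @param record A `tsp_record`.
#' @return A character vector of lines.
#' @export
serialize_ttsd <- function(record) {
  if (!inherits(record, "tsp_record")) {
    tsp_state_error("only a finalized tsp_record can be serialized")
  }
  hdr <- c(
    paste0("ttsd-dialect: ", TTSD_DIALECT),
    paste0("research_id: ", record$research_id),
    paste0("condition: ", record$condition),
    paste0("start_datetime: ", record$start_datetime),
    paste0("planned_duration_ms: ", fmt_num(record$planned_duration_ms)),
    paste0("dro_interval_ms: ", fmt_num(record$dro_interval_ms)))
  if (record$condition == "NCR") {
    hdr <- c(hdr, paste0("ncr_source: ", record$ncr_source_file))
  }
  ev <- record$events
  event_lines <- paste(fmt_num(ev$offset), ev$kind, ev$detail, sep = "\t")
  s <- record$summary
  sum_lines <- vapply(SUMMARY_FIELDS, function(f) {
    paste0(f, ": ", fmt_num(s[[f]]))
  }, character(1))
  c(hdr, event_lines, SUMMARY_SENTINEL, unname(sum_lines))
}

#' Write a record to its archive file
#'
#' Serializes the record and writes it under its archival filename (per
#' [archive_filename()]) in `dir`.
#'
#' @param record A `tsp_record`.
#' @param dir Output directory.
#' @return The path written, invisibly.
#' @export
write_ttsd <- function(record, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, archive_filename(record$research_id,
                                          record$start_datetime,
                                          record$condition))
  writeLines(serialize_ttsd(record), path, useBytes = TRUE)
  invisible(path)
}

#' Read a .ttsd file
#'
#' @param path Path to a `.ttsd` session log.
#' @return A `tsp_record`.
#' @export
read_ttsd <- function(path) {
  parse_ttsd(readLines(path, encoding = "UTF-8"))
}

parse_number <- function(x, what, line) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) && !identical(x, "NA")) {
    ttsd_parse_error(sprintf("invalid number for %s: '%s'", what, x), line)
  }
  v
}

#' Parse .ttsd text into a session record
#'
#' Inverse of [serialize_ttsd()]. Events are re-sorted defensively by
#' `(offset, kind priority)`; the summary is recomputed from the events and
#' checked against the embedded summary block (field by field, counts
#' exactly and real-valued statistics to within rounding), and mandatory
#' markers are checked (`session_start` at offset 0, a single `session_end`
#' at the maximal offset). Any violation raises a parse error naming the
#' offending line.
#'
#' @param text A character vector of lines, or a single string containing
#'   newlines.
#' @return A `tsp_record`.
#' @export
parse_ttsd <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else text
  n <- length(lines)
  if (n < 1L || !identical(lines[1], paste0("ttsd-dialect: ", TTSD_DIALECT))) {
    ttsd_parse_error(sprintf("expected dialect line 'ttsd-dialect: %s'",
                             TTSD_DIALECT), 1L)
  }
  # header
  hdr <- list()
  i <- 2L
  while (i <= n && grepl("^[a-z_]+: ", lines[i])) {
    key <- sub(":.*$", "", lines[i])
    hdr[[key]] <- sub("^[a-z_]+: ", "", lines[i])
    i <- i + 1L
  }
  required <- c("research_id", "condition", "start_datetime",
                "planned_duration_ms", "dro_interval_ms")
  missing <- setdiff(required, names(hdr))
  if (length(missing)) {
    ttsd_parse_error(paste("missing header field(s):",
                           paste(missing, collapse = ", ")), i)
  }
  if (!hdr$condition %in% TSP_CONDITIONS) {
    ttsd_parse_error(sprintf("unknown condition code '%s'", hdr$condition), 3L)
  }
  if (!grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}:\\d{2}$",
             hdr$start_datetime)) {
    ttsd_parse_error("malformed start_datetime", 4L)
  }
  dur <- parse_number(hdr$planned_duration_ms, "planned_duration_ms", 5L)
  ivl <- parse_number(hdr$dro_interval_ms, "dro_interval_ms", 6L)
  if (is.na(dur) || dur <= 0) ttsd_parse_error("nonpositive duration", 5L)
  if (is.na(ivl) || ivl <= 0) ttsd_parse_error("nonpositive DRO interval", 6L)
  if (hdr$condition == "NCR" && is.null(hdr$ncr_source)) {
    ttsd_parse_error("NCR log lacks an ncr_source header", i)
  }

  # events
  offs <- numeric(0); kinds <- character(0); details <- character(0)
  while (i <= n && !identical(lines[i], SUMMARY_SENTINEL)) {
    if (grepl("^[a-z_]+: ", lines[i])) {
      ttsd_parse_error("summary fields before the summary sentinel", i)
    }
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) == 2L) parts <- c(parts, "")
    if (length(parts) != 3L) {
      ttsd_parse_error("malformed event line (expected offset<TAB>kind<TAB>detail)", i)
    }
    if (!parts[2] %in% names(KIND_PRIORITY)) {
      ttsd_parse_error(sprintf("unknown event kind '%s'", parts[2]), i)
    }
    o <- parse_number(parts[1], "event offset", i)
    if (is.na(o) || o < 0) ttsd_parse_error("negative event offset", i)
    offs <- c(offs, o); kinds <- c(kinds, parts[2])
    details <- c(details, parts[3])
    i <- i + 1L
  }
  if (i > n) ttsd_parse_error("missing summary sentinel", n)
  sentinel_line <- i
  ev <- data.frame(offset = offs, kind = kinds, detail = details,
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$offset, KIND_PRIORITY[ev$kind]), , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev) < 2L || ev$kind[1] != "session_start" || ev$offset[1] != 0) {
    ttsd_parse_error("first event must be session_start at offset 0",
                     sentinel_line)
  }
  ends <- which(ev$kind == "session_end")
  if (length(ends) != 1L || ends != nrow(ev) ||
      ev$offset[ends] < max(ev$offset)) {
    ttsd_parse_error("session_end must be unique and at the maximal offset",
                     sentinel_line)
  }
  if (sum(ev$kind == "session_start") != 1L) {
    ttsd_parse_error("session_start must be unique", sentinel_line)
  }
  if (!ev$detail[ends] %in% END_REASONS) {
    ttsd_parse_error(sprintf("unknown end reason '%s'", ev$detail[ends]),
                     sentinel_line)
  }

  # summary block
  i <- i + 1L
  emb <- list()
  while (i <= n && grepl("^[a-z_]+: ", lines[i])) {
    key <- sub(":.*$", "", lines[i])
    emb[[key]] <- parse_number(sub("^[a-z_]+: ", "", lines[i]), key, i)
    i <- i + 1L
  }
  missing <- setdiff(SUMMARY_FIELDS, names(emb))
  if (length(missing)) {
    ttsd_parse_error(paste("missing summary field(s):",
                           paste(missing, collapse = ", ")), i - 1L)
  }
  undeliv <- emb$undelivered_reward_count
  if (is.na(undeliv) || undeliv < 0 || undeliv != round(undeliv)) {
    ttsd_parse_error("undelivered_reward_count must be a non-negative integer",
                     sentinel_line + 3L)
  }
  recomputed <- compute_summary(ev, undeliv)
  for (f in c("tic_count", "reward_count", "duration_ms")) {
    if (recomputed[[f]] != emb[[f]]) {
      ttsd_parse_error(sprintf(
        "summary field %s (%s) disagrees with the event lines (%s)",
        f, fmt_num(emb[[f]]), fmt_num(recomputed[[f]])), sentinel_line)
    }
  }
  for (f in c("tics_per_minute", "mean_inter_tic_interval_ms",
              "longest_tic_free_interval_ms")) {
    a <- recomputed[[f]]; b <- emb[[f]]
    ok <- (is.na(a) && is.na(b)) ||
      (!is.na(a) && !is.na(b) && abs(a - b) <= 1e-6 * max(1, abs(a)))
    if (!ok) {
      ttsd_parse_error(sprintf(
        "summary field %s disagrees with the event lines", f), sentinel_line)
    }
  }

  structure(
    list(research_id = hdr$research_id,
         start_datetime = hdr$start_datetime,
         condition = hdr$condition,
         planned_duration_ms = dur,
         dro_interval_ms = ivl,
         ncr_source_file = hdr$ncr_source %||% NA_character_,
         events = ev,
         summary = recomputed),
    class = "tsp_record")
}
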