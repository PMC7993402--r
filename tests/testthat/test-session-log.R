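test_that("serialization produces one line per event plus header and summary", {
  cfg <- session_config("DRZ", 60000, "au5")
  rec <- run_session(cfg, c(3000, 7000), "2020-06-22 15:31:25")
  lines <- serialize_ttsd(rec)
  expect_equal(lines[1], "ttsd-dialect: ttw-spec-1")
  event_lines <- grep("^[0-9]+\t", lines, value = TRUE)
  expect_equal(length(event_lines), nrow(rec$events))
  expect_equal(sum(grepl("\ttic\t", event_lines)), 2L)
  expect_true("=== summary ===" %in% lines)
  expect_true(any(grepl("^tic_count: 2$", lines)))
  expect_true(any(grepl("^reward_count: ", lines)))
  expect_true(any(grepl("^duration_ms: 60000$", lines)))
  # deterministic bytes
  expect_identical(lines, serialize_ttsd(rec))
})

test_that("serialize/parse round-trips a record field for field", {
  cfg <- session_config("DRZ", 60000, "au5")
  rec <- run_session(cfg, c(3000, 7000), "2020-06-22 15:31:25")
  back <- parse_ttsd(serialize_ttsd(rec))
  expect_equal(back, rec)
  # and the text itself is a fixed point
  expect_identical(serialize_ttsd(back), serialize_ttsd(rec))
})

test_that("round-trip identity holds over randomized records", {
  for (seed in 1:40) {
    rec <- suppressWarnings(random_record(seed))
    back <- parse_ttsd(serialize_ttsd(rec))
    expect_equal(back, rec, label = sprintf("seed %d", seed))
  }
})

test_that("file write/read round-trips through the archive name", {
  dir <- withr::local_tempdir()
  rec <- run_session(session_config("DRZ", 30000, "au5"), 4000,
                     "2020-06-22 15:31:25")
  path <- write_ttsd(rec, dir)
  expect_equal(basename(path), "au5_20200622-153125_DRZ.ttsd")
  expect_equal(read_ttsd(path), rec)
})

test_that("parser rejects malformed logs with line-numbered errors", {
  rec <- run_session(session_config("DRZ", 30000, "au5"), 4000,
                     "2020-06-22 15:31:25")
  lines <- serialize_ttsd(rec)

  bad <- lines; bad[1] <- "ttsd-dialect: something-else"
  expect_error(parse_ttsd(bad), "line 1", class = "ttsd_parse_error")

  bad <- lines; bad[3] <- "condition: DRO"
  expect_error(parse_ttsd(bad), "condition", class = "ttsd_parse_error")

  # summary tic count disagreeing with the event lines
  bad <- lines
  i <- grep("^tic_count:", bad)
  bad[i] <- "tic_count: 5"
  expect_error(parse_ttsd(bad), "tic_count", class = "ttsd_parse_error")

  # missing sentinel
  bad <- lines[lines != "=== summary ==="]
  expect_error(parse_ttsd(bad), "sentinel", class = "ttsd_parse_error")

  # unknown event kind
  bad <- lines
  i <- grep("\ttic\t", bad)[1]
  bad[i] <- sub("\ttic\t", "\tsneeze\t", bad[i])
  expect_error(parse_ttsd(bad), "kind", class = "ttsd_parse_error")

  # session_end not at the maximal offset
  bad <- lines
  i <- grep("\tsession_end\t", bad)
  bad[i] <- "2000\tsession_end\trater ended"
  expect_error(parse_ttsd(bad), "session_end", class = "ttsd_parse_error")
})

test_that("events in a serialized log appear in non-decreasing offset order", {
  for (seed in 1:10) {
    rec <- suppressWarnings(random_record(seed + 400))
    lines <- serialize_ttsd(rec)
    offs <- as.numeric(sub("\t.*$", "", grep("^[0-9]", lines, value = TRUE)))
    expect_true(all(diff(offs) >= 0))
  }
})

test_that("archive filenames reproduce the published naming convention", {
  expect_identical(archive_filename("au5", "2020-06-22 15:30:43", "baseline"),
                   "au5_20200622-153043_baseline.ttsd")
  expect_identical(archive_filename("au5", "2020-06-22 15:31:25", "DRZ"),
                   "au5_20200622-153125_DRZ.ttsd")
  expect_identical(archive_filename("au5", "2020-06-22 15:32:14", "NCR"),
                   "au5_20200622-153214_NCR.ttsd")
  expect_error(archive_filename("a_5", "2020-06-22 15:30:43", "baseline"),
               class = "tsp_config_error")
})

test_that("archive filenames are injective and re-parseable", {
  ids <- c("au5", "bu7", "x9")
  stamps <- c("2020-06-22 15:30:43", "2021-01-02 03:04:05")
  conds <- c("baseline", "verbal", "DRZ", "NCR")
  grid <- expand.grid(id = ids, dt = stamps, cond = conds,
                      stringsAsFactors = FALSE)
  names <- mapply(archive_filename, grid$id, grid$dt, grid$cond)
  expect_equal(anyDuplicated(names), 0L)
  for (i in seq_len(nrow(grid))) {
    p <- parse_archive_filename(names[i])
    expect_equal(p$research_id, grid$id[i])
    expect_equal(p$start_datetime, grid$dt[i])
    expect_equal(p$condition, grid$cond[i])
  }
})
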