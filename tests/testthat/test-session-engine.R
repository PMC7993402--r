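test_that("session construction and configuration validation", {
  st <- start_session(session_config("baseline", 300000, "au5"))
  expect_true(st$live)
  expect_equal(nrow(st$events), 1L)
  expect_equal(st$events$kind, "session_start")
  expect_equal(st$events$offset, 0)
  expect_equal(st$last_reset, 0)

  expect_error(session_config("NCR", 300000, "au5"),
               class = "tsp_config_error")
  expect_error(session_config("baseline", -1, "au5"),
               class = "tsp_config_error")
  expect_error(session_config("DRZ", 300000, "au5", dro_interval_ms = 0),
               class = "tsp_config_error")
  expect_error(session_config("DRZ", 300000, "a_5"),
               class = "tsp_config_error")
  expect_error(session_config("baseline", 300000, "au5",
                              ncr_source = reward_schedule(1000, "au5")),
               class = "tsp_config_error")
})

test_that("first DRZ reward falls due one interval after the last reset", {
  st <- start_session(session_config("DRZ", 300000, "au5"))
  expect_equal(next_reward_due(st), 10000)

  # a tic restarts the countdown: tics at 3000 and 7000 push the first
  # reward to 17000 (frozen from the 1-ms-step oracle)
  cfg <- session_config("DRZ", 300000, "au5")
  rec <- run_session(cfg, c(3000, 7000), "2024-01-01 09:00:00")
  expect_equal(event_offsets(rec, "reward")[1], 17000)
  orc <- oracle_session("DRZ", 300000, 10000, tics = c(3000, 7000))
  expect_equal(rec$events, orc)
})

test_that("next_reward_due gates on condition and consumes NCR offsets", {
  expect_null(next_reward_due(
    start_session(session_config("baseline", 300000, "au5"))))
  expect_null(next_reward_due(
    start_session(session_config("verbal", 300000, "au5"))))

  cfg <- make_ncr_config(reward_schedule(c(10000, 20000, 35000), "au5"),
                         300000, "au5")
  st <- start_session(cfg)
  st <- advance_session(st, 15000)$state
  expect_equal(next_reward_due(st), 20000)
})

test_that("advance emits due rewards in order and terminates on time", {
  cfg <- session_config("DRZ", 300000, "au5")
  st <- start_session(cfg)
  adv <- advance_session(st, 9999)
  expect_equal(nrow(adv$emitted), 0L)

  adv <- advance_session(adv$state, 300000)
  rewards <- adv$emitted[adv$emitted$kind == "reward", ]
  expect_equal(rewards$offset, seq(10000, 300000, by = 10000))
  expect_false(adv$state$live)
  expect_equal(tail(adv$state$events, 1)$kind, "session_end")
  expect_equal(tail(adv$state$events, 1)$detail, "duration elapsed")

  base <- advance_session(
    start_session(session_config("baseline", 300000, "au5")), 300000)
  expect_equal(base$emitted$kind, "session_end")
})

test_that("liveness is enforced after session end", {
  st <- start_session(session_config("DRZ", 300000, "au5"))
  st <- advance_session(st, 300000)$state
  expect_error(record_tic(st, 1000), class = "tsp_state_error")
  expect_error(advance_session(st, 300001), class = "tsp_state_error")
  expect_error(end_session(st, 300000), class = "tsp_state_error")

  st2 <- start_session(session_config("DRZ", 300000, "au5"))
  rec <- end_session(st2, 150000, "rater ended")
  expect_equal(rec$summary$duration_ms, 150000)
  expect_equal(tail(rec$events, 1)$detail, "rater ended")
})

test_that("end_session clamps to the planned duration and validates reasons", {
  st <- start_session(session_config("DRZ", 300000, "au5"))
  rec <- end_session(st, 400000, "connection closed")
  end <- rec$events[rec$events$kind == "session_end", ]
  expect_equal(end$offset, 300000)
  expect_equal(event_offsets(rec, "reward"), seq(10000, 300000, 10000))

  st <- start_session(session_config("baseline", 10000, "au5"))
  expect_error(end_session(st, 5000, "browser crashed"),
               class = "tsp_config_error")
})

test_that("a tic at the exact due offset pre-empts the DRZ reward", {
  cfg <- session_config("DRZ", 40000, "au5")
  rec <- run_session(cfg, 10000, "2024-01-01 09:00:00")
  # countdown restarts at the tic: rewards at 20000, 30000, 40000 only
  expect_equal(event_offsets(rec, "reward"), c(20000, 30000, 40000))
  expect_equal(rec$events, oracle_session("DRZ", 40000, tics = 10000))
})

test_that("NCR reward times are unaffected by tics", {
  sched <- reward_schedule(c(10000, 20000), "au5")
  cfg <- make_ncr_config(sched, 300000, "au5")
  rec <- run_session(cfg, 9999, "2024-01-01 09:00:00")
  expect_equal(event_offsets(rec, "reward"), c(10000, 20000))

  # even a tic at the exact reward offset leaves the replay intact,
  # ordered tic first
  rec2 <- run_session(cfg, 10000, "2024-01-01 09:00:00")
  expect_equal(event_offsets(rec2, "reward"), c(10000, 20000))
  at <- rec2$events[rec2$events$offset == 10000, "kind"]
  expect_equal(at, c("tic", "reward"))
})

test_that("engine reproduces the 1-ms-step oracle on random sessions", {
  for (seed in 1:100) {
    cs <- random_session_case(seed)
    rec <- run_session(cs$config, cs$tics, "2024-01-01 09:00:00")
    orc <- oracle_session(cs$condition, cs$duration_ms, cs$dro_interval_ms,
                          tics = cs$tics)
    expect_equal(rec$events, orc, label = sprintf("seed %d", seed))
  }
})

test_that("engine matches the oracle on NCR replays with random tics", {
  for (seed in 1:25) {
    cs <- random_session_case(seed + 5000, conditions = "DRZ")
    src <- run_session(cs$config, cs$tics, "2024-01-01 09:00:00")
    sched <- extract_reward_schedule(src)
    ncr_tics <- simulate_tics(
      tic_stream_model(base_rate_per_min = 12, seed = seed + 7000L),
      cs$duration_ms)
    cfg <- make_ncr_config(sched, cs$duration_ms, "sub1",
                           dro_interval_ms = cs$dro_interval_ms)
    rec <- run_session(cfg, ncr_tics, "2024-01-01 09:00:00")
    orc <- oracle_session("NCR", cs$duration_ms, cs$dro_interval_ms,
                          tics = ncr_tics, ncr_offsets = sched$offsets)
    expect_equal(rec$events, orc, label = sprintf("seed %d", seed))
  }
})

test_that("DRO safety, spacing and completeness invariants hold", {
  for (seed in 1:60) {
    cs <- random_session_case(seed + 9000, conditions = "DRZ")
    rec <- run_session(cs$config, cs$tics, "2024-01-01 09:00:00")
    rewards <- event_offsets(rec, "reward")
    tics <- event_offsets(rec, "tic")
    ivl <- cs$dro_interval_ms
    # safety: no tic inside the interval that earned each reward
    for (r in rewards) {
      expect_false(any(tics > r - ivl & tics <= r))
    }
    # spacing: consecutive rewards at least one interval apart
    if (length(rewards) >= 2) {
      expect_true(all(diff(rewards) >= ivl))
    }
  }
  # completeness: tic-free sessions earn exactly floor(T / interval)
  for (dur in c(25000, 60000, 99999)) {
    for (ivl in c(4000, 10000)) {
      rec <- run_session(session_config("DRZ", dur, "s1",
                                        dro_interval_ms = ivl),
                         numeric(0), "2024-01-01 09:00:00")
      expect_equal(rec$summary$reward_count, floor(dur / ivl))
    }
  }
})

test_that("baseline and verbal sessions never contain rewards", {
  for (seed in 1:30) {
    cs <- random_session_case(seed + 20000,
                              conditions = c("baseline", "verbal"))
    rec <- run_session(cs$config, cs$tics, "2024-01-01 09:00:00")
    expect_equal(rec$summary$reward_count, 0L)
    expect_false(any(rec$events$kind == "reward"))
  }
})
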