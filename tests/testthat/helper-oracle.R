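# Independent brute-force oracle: steps the session clock one millisecond
# at a time, restarting the tic-free countdown at every tic and every
# reward. At each step tics are processed before the reward check, so a tic
# landing exactly on a due time pre-empts the reward (DRZ); NCR rewards fire
# at their source offsets regardless of tics. Deliberately naive, shares no
# code with the engine.
oracle_session <- function(condition, duration_ms, dro_interval_ms = 10000,
                           tics = numeric(0), ncr_offsets = numeric(0)) {
  Tms <- as.integer(duration_ms)
  tic_count <- integer(Tms)
  for (t in tics) tic_count[t] <- tic_count[t] + 1L
  ncr_flag <- logical(Tms)
  for (o in ncr_offsets) if (o <= Tms) ncr_flag[o] <- TRUE
  off <- numeric(0); kind <- character(0)
  last_reset <- 0
  for (m in seq_len(Tms)) {
    k <- tic_count[m]
    if (k > 0L) {
      off <- c(off, rep(m, k)); kind <- c(kind, rep("tic", k))
      last_reset <- m
    }
    if (condition == "DRZ") {
      if (m == last_reset + dro_interval_ms) {
        off <- c(off, m); kind <- c(kind, "reward")
        last_reset <- m
      }
    } else if (condition == "NCR") {
      if (ncr_flag[m]) {
        off <- c(off, m); kind <- c(kind, "reward")
        last_reset <- m
      }
    }
  }
  data.frame(offset = c(0, off, Tms),
             kind = c("session_start", kind, "session_end"),
             detail = c(rep("", length(off) + 1L), "duration elapsed"),
             stringsAsFactors = FALSE)
}

event_offsets <- function(record, what) {
  record$events$offset[record$events$kind == what]
}

# Random session case for property tests: short sessions keep the 1-ms
# oracle affordable.
random_session_case <- function(seed, conditions = c("baseline", "verbal",
                                                     "DRZ")) {
  set.seed(seed)
  dur <- sample(15:45, 1) * 1000
  ivl <- sample(3:10, 1) * 1000
  rate <- runif(1, 4, 30)
  cond <- sample(conditions, 1)
  tics <- simulate_tics(
    tic_stream_model(base_rate_per_min = rate, seed = seed + 100000L), dur)
  list(config = session_config(cond, dur, "sub1", dro_interval_ms = ivl),
       tics = tics, duration_ms = dur, dro_interval_ms = ivl,
       condition = cond)
}

# Random finalized record across all four conditions (NCR sources its
# schedule from a fresh DRZ session of the same subject).
random_record <- function(seed) {
  set.seed(seed)
  cond <- sample(c("baseline", "verbal", "DRZ", "NCR"), 1)
  dur <- sample(20:60, 1) * 1000
  ivl <- sample(c(5, 10), 1) * 1000
  rate <- runif(1, 2, 20)
  dt <- sprintf("2024-0%d-1%d 0%d:%02d:%02d", sample(1:9, 1), sample(0:9, 1),
                sample(1:9, 1), sample(0:59, 1), sample(0:59, 1))
  tics <- simulate_tics(
    tic_stream_model(base_rate_per_min = rate, seed = seed + 200000L), dur)
  if (cond == "NCR") {
    src_tics <- simulate_tics(
      tic_stream_model(base_rate_per_min = rate, seed = seed + 300000L), dur)
    src <- run_session(session_config("DRZ", dur, "sub1",
                                      dro_interval_ms = ivl),
                       src_tics, "2024-01-01 09:00:00")
    cfg <- make_ncr_config(extract_reward_schedule(src), dur, "sub1",
                           dro_interval_ms = ivl)
  } else {
    cfg <- session_config(cond, dur, "sub1", dro_interval_ms = ivl)
  }
  run_session(cfg, tics, dt)
}
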