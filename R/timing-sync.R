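#' Round-trip lag model
#'
#' Distribution of client-server round-trip times (RTT) used by the
#' check-in simulation. Each check-in samples one RTT; the forward and
#' return legs split it by an independent uniform(0, 1) fraction, so the
#' client's symmetric rtt/2 compensation carries an error of
#' (return - forward)/2.
#'
#' @param distribution `"constant"`, `"uniform"` or `"lognormal"`.
#' @param rtt_ms Constant RTT in ms (constant model; 0 is the exact
#'   virtual-clock limit).
#' @param min_ms,max_ms Bounds in ms (uniform model).
#' @param meanlog,sdlog Log-scale parameters (lognormal model, ms).
#' @return An object of class `lag_model`.
#' @export
#' @examples
#' lag_model("uniform", min_ms = 20, max_ms = 200)
lag_model <- function(distribution = c("constant", "uniform", "lognormal"),
                      rtt_ms = 0, min_ms = 20, max_ms = 200,
                      meanlog = log(80), sdlog = 0.5) {
  distribution <- match.arg(distribution)
  if (distribution == "constant" &&
      (!is_scalar_number(rtt_ms) || rtt_ms < 0)) {
    tsp_config_error("constant RTT must be >= 0")
  }
  if (distribution == "uniform" &&
      (!is_scalar_number(min_ms) || !is_scalar_number(max_ms) ||
       min_ms < 0 || max_ms < min_ms)) {
    tsp_config_error("uniform RTT bounds must satisfy 0 <= min <= max")
  }
  structure(
    list(distribution = distribution, rtt_ms = rtt_ms,
         min_ms = min_ms, max_ms = max_ms,
         meanlog = meanlog, sdlog = sdlog),
    class = "lag_model")
}

sample_rtt <- function(model, n = 1L) {
  switch(model$distribution,
         constant = rep(model$rtt_ms, n),
         uniform = stats::runif(n, model$min_ms, model$max_ms),
         lognormal = stats::rlnorm(n, model$meanlog, model$sdlog))
}

#' Time remaining until the next reward
#'
#' The server's answer to a client check-in: the time remaining until the
#' next reward is due, floored at zero, or `NULL` when no reward is pending
#' (baseline/verbal, or an exhausted NCR schedule).
#'
#' @param state A live `tsp_state` (the server's view of the session).
#' @param now Server clock, ms from session start.
#' @return Milliseconds remaining, or `NULL`.
#' @export
remaining_until_reward <- function(state, now) {
  due <- next_reward_due(state)
  if (is.null(due)) return(NULL)
  max(0, due - now)
}

#' Client re-poll delay with round-trip compensation
#'
#' The client schedules its next check-in after the server-reported
#' remaining time minus half the measured round trip (the one-way lag
#' estimate under a symmetric link), floored at zero.
#'
#' @param remaining Server-reported remaining time, ms (>= 0).
#' @param rtt Measured round-trip time of the exchange, ms (>= 0).
#' @return Delay in ms before the next check-in.
#' @export
#' @examples
#' next_check_delay(10000, 100) # 9950
next_check_delay <- function(remaining, rtt) {
  if (!is_scalar_number(remaining) || remaining < 0) {
    tsp_config_error("remaining must be >= 0")
  }
  if (!is_scalar_number(rtt) || rtt < 0) {
    tsp_config_error("rtt must be >= 0")
  }
  max(0, remaining - rtt / 2)
}

#' Simulate the lag-compensated client/server check-in loop
#'
#' Discrete-event simulation, on a virtual clock, of the protocol that
#' synchronizes reward delivery between a reward-displaying client and the
#' server holding the session state. The client polls; the request arrives
#' after a sampled forward delay; the server applies any tics signalled up
#' to that instant, advances the engine, and answers with the time
#' remaining until the next reward. The client, knowing the measured round
#' trip of the exchange, sleeps `remaining - rtt/2` (see
#' [next_check_delay()]; without compensation it sleeps the full
#' `remaining`) and delivers the reward at its wake moment, then checks
#' back in. A tic signalled between the server's answer and the due time
#' cancels the pending delivery (the server is authoritative); consecutive
#' polls are kept at least `poll_floor_ms` apart.
#'
#' With zero lag the delivered offsets coincide exactly with the engine's
#' reward offsets; with a constant round trip the absolute delivery error
#' is bounded by rtt/2.
#'
#' @param config A [session_config()].
#' @param tic_offsets Sorted tic offsets in ms (the rater's signals).
#' @param lag A [lag_model()].
#' @param seed Integer seed; the simulation is reproducible given the seed.
#' @param compensate Logical; apply the rtt/2 compensation (default) or
#'   re-poll after the uncompensated remaining time.
#' @param poll_floor_ms Minimum spacing between consecutive polls, ms.
#' @return A `delivery_trace` data frame with one row per reward emitted by
#'   the engine: `scheduled` (the engine due time), `delivered` (client
#'   display time; `NA` if the session ended before the client woke) and
#'   `error = delivered - scheduled`. The finalized `tsp_record` is
#'   attached as attribute `"record"`.
#' @export
run_checkin_loop <- function(config, tic_offsets = numeric(0),
                             lag = lag_model("constant", rtt_ms = 0),
                             seed = 1L, compensate = TRUE,
                             poll_floor_ms = 10) {
  if (!inherits(config, "tsp_config")) {
    tsp_config_error("config must be a tsp_config")
  }
  if (!inherits(lag, "lag_model")) tsp_config_error("lag must be a lag_model")
  if (!is.numeric(tic_offsets)) {
    tsp_config_error("tic_offsets must be numeric")
  }
  dur <- config$planned_duration_ms
  tics <- sort(tic_offsets)
  tics <- tics[tics > 0 & tics < dur]

  with_seed(seed, {
    state <- start_session(config)
    tic_i <- 1L
    clock <- 0            # client time of the next poll
    committed <- list()   # due offset (as character) -> client wake time
    scheduled <- numeric(0)
    delivered <- numeric(0)

    # Server-side sync: signal tics up to `at`, advance the engine, and
    # pair any newly emitted rewards with their client delivery moments.
    sync <- function(at) {
      n0 <- sum(state$events$kind == "reward")
      while (tic_i <= length(tics) && tics[tic_i] <= at) {
        state <<- record_tic(state, tics[tic_i])
        tic_i <<- tic_i + 1L
      }
      adv <- advance_session(state, at)
      state <<- adv$state
      rew <- state$events$offset[state$events$kind == "reward"]
      rew[seq_along(rew) > n0]
    }

    repeat {
      if (clock >= dur) break
      rtt <- sample_rtt(lag)
      split <- stats::runif(1)
      d_fwd <- rtt * split
      s <- clock + d_fwd        # server receipt time
      if (s >= dur) break
      t_receipt <- clock + rtt  # client receipt of the response
      new_rewards <- sync(s)
      for (d in new_rewards) {
        scheduled <- c(scheduled, d)
        delivered <- c(delivered,
                       committed[[as.character(d)]] %||% t_receipt)
      }
      r <- remaining_until_reward(state, s)
      if (is.null(r)) break     # no reward will ever be pending again
      delay <- if (compensate) next_check_delay(r, rtt) else r
      wake <- t_receipt + delay
      due <- s + r              # true due time per the server's state
      if (due <= dur) {
        key <- as.character(due)
        cancelled <- config$condition == "DRZ" &&
          any(tics > s & tics <= due)
        if (!cancelled && is.null(committed[[key]])) {
          committed[[key]] <- wake
        }
      }
      clock <- max(wake, clock + poll_floor_ms)
    }

    # Flush the end of the session: remaining tics, rewards due by the
    # planned duration, and session_end.
    new_rewards <- sync(dur)
    for (d in new_rewards) {
      scheduled <- c(scheduled, d)
      delivered <- c(delivered, committed[[as.character(d)]] %||% NA_real_)
    }
    record <- finalize_record(state)
    trace <- data.frame(scheduled = scheduled, delivered = delivered,
                        error = delivered - scheduled)
    class(trace) <- c("delivery_trace", "data.frame")
    attr(trace, "record") <- record
    trace
  })
}
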