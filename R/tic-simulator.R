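#' Stochastic tic-stream model
#'
#' Point-process generator of synthetic tic streams so the engine, log
#' format and timing simulation can be exercised without human data.
#' `poisson` draws exponential inter-tic intervals; `gamma_renewal` draws
#' gamma-distributed intervals with the given shape (shape > 1 gives more
#' regular streams, shape < 1 burstier ones), both with mean `1/rate`. The
#' suppression multiplier thins the rate under conditions where the subject
#' is suppressing (DRZ, verbal); the defaults — 6 tics/min with multiplier
#' 0.3 — are plausible magnitudes for a child with a tic disorder, chosen to
#' exercise the machinery, not fitted to any subject.
#'
#' @param process `"poisson"` or `"gamma_renewal"`.
#' @param base_rate_per_min Baseline tic rate, tics per minute (> 0).
#' @param shape Gamma shape parameter (> 0; gamma_renewal only).
#' @param suppression_multiplier Factor in (0, 1] applied to the rate when
#'   the stream is generated under suppression; 1 leaves it unchanged.
#' @param seed Integer seed; generation is reproducible given the seed.
#' @return An object of class `tic_stream_model`.
#' @export
tic_stream_model <- function(process = c("poisson", "gamma_renewal"),
                             base_rate_per_min = 6, shape = 2,
                             suppression_multiplier = 1, seed = 1L) {
  process <- match.arg(process)
  if (!is_scalar_number(base_rate_per_min) || base_rate_per_min <= 0) {
    tsp_config_error("base_rate_per_min must be > 0")
  }
  if (!is_scalar_number(shape) || shape <= 0) {
    tsp_config_error("shape must be > 0")
  }
  if (!is_scalar_number(suppression_multiplier) ||
      suppression_multiplier <= 0 || suppression_multiplier > 1) {
    tsp_config_error("suppression_multiplier must be in (0, 1]")
  }
  structure(
    list(process = process, base_rate_per_min = base_rate_per_min,
         shape = shape, suppression_multiplier = suppression_multiplier,
         seed = as.integer(seed)),
    class = "tic_stream_model")
}

#' Simulate a tic stream
#'
#' Draws tic offsets over `(0, duration_ms)`, rounded to whole
#' milliseconds, sorted and reproducible given the model's seed.
#'
#' @param model A [tic_stream_model()].
#' @param duration_ms Stream length in ms (> 0).
#' @param suppressed Logical; apply the model's suppression multiplier
#'   (used when emulating DRZ or verbal-instruction sessions).
#' @return Numeric vector of tic offsets in ms.
#' @export
#' @examples
#' m <- tic_stream_model(base_rate_per_min = 6, seed = 42)
#' length(simulate_tics(m, 300000)) # around 30
simulate_tics <- function(model, duration_ms, suppressed = FALSE) {
  if (!inherits(model, "tic_stream_model")) {
    tsp_config_error("model must be a tic_stream_model")
  }
  if (!is_scalar_number(duration_ms) || duration_ms <= 0) {
    tsp_config_error("duration_ms must be > 0")
  }
  rate <- model$base_rate_per_min / 60000
  if (suppressed) rate <- rate * model$suppression_multiplier
  draw_gaps <- function(k) {
    if (model$process == "poisson") stats::rexp(k, rate)
    else stats::rgamma(k, shape = model$shape, rate = model$shape * rate)
  }
  with_seed(model$seed, {
    offsets <- numeric(0)
    cur <- 0
    repeat {
      k <- max(16L, ceiling(rate * duration_ms * 1.5))
      tt <- cur + cumsum(draw_gaps(k))
      offsets <- c(offsets, tt)
      cur <- offsets[length(offsets)]
      if (cur > duration_ms) break
    }
    offsets <- round(offsets)
    offsets[offsets >= 1 & offsets < duration_ms]
  })
}

#' Rater-latency model
#'
#' The rater marks each tic "immediately", but a human reaction lag
#' separates the tic from the keypress. This model perturbs true tic
#' offsets by a nonnegative i.i.d. latency: constant, or lognormal with the
#' given mean (`meanlog` is derived from the mean and `sdlog`).
#'
#' @param distribution `"constant"` or `"lognormal"`.
#' @param mean_ms Mean latency in ms (>= 0).
#' @param sdlog Log-scale spread of the lognormal latency.
#' @return An object of class `rater_latency_model`.
#' @export
rater_latency_model <- function(distribution = c("constant", "lognormal"),
                                mean_ms = 0, sdlog = 0.5) {
  distribution <- match.arg(distribution)
  if (!is_scalar_number(mean_ms) || mean_ms < 0) {
    tsp_config_error("mean_ms must be >= 0")
  }
  structure(list(distribution = distribution, mean_ms = mean_ms,
                 sdlog = sdlog),
            class = "rater_latency_model")
}

#' Perturb tic offsets by rater reaction latency
#'
#' Shifts each offset by an i.i.d. nonnegative latency drawn from the
#' model, re-sorts, and rounds to whole milliseconds. Reproducible given
#' the seed; a constant latency of zero is the identity.
#'
#' @param offsets Sorted tic offsets in ms.
#' @param model A [rater_latency_model()].
#' @param seed Integer seed.
#' @return Perturbed, sorted offsets in ms.
#' @export
apply_rater_latency <- function(offsets, model, seed = 1L) {
  if (!inherits(model, "rater_latency_model")) {
    tsp_config_error("model must be a rater_latency_model")
  }
  if (!length(offsets)) return(numeric(0))
  with_seed(seed, {
    lat <- switch(model$distribution,
                  constant = rep(model$mean_ms, length(offsets)),
                  lognormal = if (model$mean_ms == 0) {
                    rep(0, length(offsets))
                  } else {
                    stats::rlnorm(length(offsets),
                                  meanlog = log(model$mean_ms) -
                                    model$sdlog^2 / 2,
                                  sdlog = model$sdlog)
                  })
    round(sort(offsets + lat))
  })
}

#' Simulate a complete session
#'
#' Generates a tic stream from the model (thinned by the suppression
#' multiplier when the condition is DRZ or verbal) and runs it through the
#' session engine, yielding an archivable record. This is how `.ttsd`
#' fixtures are produced without human data.
#'
#' @param config A [session_config()].
#' @param model A [tic_stream_model()].
#' @param start_datetime Passed to [start_session()].
#' @return A `tsp_record`.
#' @export
simulate_session <- function(config, model,
                             start_datetime = Sys.time()) {
  if (!inherits(config, "tsp_config")) {
    tsp_config_error("config must be a tsp_config")
  }
  tics <- simulate_tics(model, config$planned_duration_ms,
                        suppressed = config$condition %in% c("DRZ", "verbal"))
  run_session(config, tics, start_datetime)
}
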