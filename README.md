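# ticsession

Headless R implementation of the **tic suppression paradigm (TSP)** session
protocol used in tic-disorder research (Tourette syndrome, Provisional Tic
Disorder and related conditions). A trained rater marks each observed tic;
the software runs the session under one of four experimental conditions,
delivers rewards when the contingency calls for them, and archives every
session as a plain-text log for later analysis:

* **baseline** — observation only;
* **verbal** — instruction to suppress; no rewards;
* **DRZ** (the DRO condition) — differential reinforcement of zero-rate
  ticcing: a reward after every interval of length *I* (default
  *I* = 10 s) containing no tic. The countdown anchor is
  `last_reset = max(session start, last tic, last reward)` and a reward
  falls due at exactly `last_reset + I`, a tic at the due instant
  pre-empting the reward;
* **NCR** — noncontingent reinforcement: rewards replayed at the offsets
  recorded in an earlier session of the same subject, irrespective of
  current tics.

The package also models the timing problem of running the paradigm
*remotely*: a reward-displaying client that checks in with the session
server, learns the remaining time *r* until the next reward, and re-polls
after `r − RTT/2` (half the measured round trip estimating the one-way
lag). `run_checkin_loop()` simulates this protocol by discrete events on a
virtual clock and measures each reward's delivery error; under round-trip
lags uniform on (20, 200) ms the median absolute error is ~22 ms, within
the 50 ms that remote reward delivery is expected to hold.

Everything is deterministic given seeds: the engine runs on integer
milliseconds from session start, synthetic tic streams come from seeded
Poisson/gamma-renewal models, and sessions archive as `.ttsd` text files
named `<research_id>_<YYYYMMDD-HHMMSS>_<condition>.ttsd`.

## Worked example

```r
library(ticsession)

cfg   <- session_config("DRZ", 300000, "au5")     # 5-min DRO session
model <- tic_stream_model(base_rate_per_min = 6,  # simulated subject
                          suppression_multiplier = 0.3, seed = 42)
rec   <- simulate_session(cfg, model, start_datetime = "2020-06-22 15:31:25")
rec
#> TSP session record: DRZ, subject au5, started 2020-06-22 15:31:25
#>   37 events over 300000 ms
#>   tics: 11 (2.2/min)  rewards: 24 delivered, 0 undelivered
#>   longest tic-free interval: 63566 ms  mean inter-tic interval: 22982.3 ms

base <- simulate_session(session_config("baseline", 300000, "au5"),
                         model, "2020-06-22 15:30:43")
suppression_ratio(rec, base)   # DRZ rate / baseline rate; < 1 = suppression
#> [1] 0.3666667

write_ttsd(rec, "archive")
#> archive/au5_20200622-153125_DRZ.ttsd
```

The subject tics 11 times in 5 minutes under reinforcement (2.2/min,
0.37 times the baseline rate, i.e. substantial suppression) and earns 24 of
a possible 30 rewards. The archived file begins:

```
ttsd-dialect: ttw-spec-1
research_id: au5
condition: DRZ
start_datetime: 2020-06-22 15:31:25
planned_duration_ms: 300000
dro_interval_ms: 10000
0	session_start
6611	tic
16611	reward
26611	reward
```

(the first reward comes 10 s after the tic at 6611 ms restarted the
countdown), and ends with a `=== summary ===` block that `parse_ttsd()`
verifies against the event lines. An NCR session replays such a log:

```r
sched <- extract_reward_schedule(read_ttsd("archive/au5_20200622-153125_DRZ.ttsd"))
ncr   <- run_session(make_ncr_config(sched, 300000, "au5"), tic_offsets = c(9999))
```

Timing of remote delivery:

```r
tr <- run_checkin_loop(cfg, simulate_tics(model, 300000),
                       lag_model("uniform", min_ms = 20, max_ms = 200), seed = 1)
median(abs(tr$error))
#> [1] 23.5  # ms
```

A command-line interface over the same functions is installed at
`system.file("cli", "ttsd.R", package = "ticsession")` with subcommands
`run` (live keypress sessions), `simulate`, `replay` and `summarize`.

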