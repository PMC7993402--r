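---
title: "Running tic suppression paradigm sessions with ticsession"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Running tic suppression paradigm sessions with ticsession}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ticsession)
```

## The paradigm

The tic suppression paradigm (TSP) quantifies how well a person with a tic
disorder can voluntarily suppress tics. A trained rater watches the subject
and marks every tic the moment it is observed; the subject is run through
several short sessions under different contingencies:

* **baseline** — observation only; no instruction, no rewards;
* **verbal** — the subject is asked to suppress tics; no rewards;
* **DRZ** — differential reinforcement of zero-rate ticcing (DRO): a reward
  is dispensed after every fixed-length interval containing no tic, 10 s by
  default. `DRZ` is the condition code used in archive filenames;
* **NCR** — noncontingent reinforcement: rewards are delivered at the same
  offsets (relative to session start) at which they were delivered in an
  earlier session of the same subject, irrespective of current tics. The
  comparison of DRZ with NCR isolates the contribution of the contingency
  itself from the mere presence of rewards.

`ticsession` implements this protocol as a headless, deterministic state
machine, so sessions can be driven by a live rater at a terminal, by
archived logs, or by simulated tic streams in tests.

## The session engine and its time base

All within-session times are milliseconds from session start on a
monotonic, virtual clock; the only wall-clock value is the start datetime
recorded once at `start_session()`, which names the archive file. This
makes every session exactly reproducible in tests.

The DRO countdown is anchored at `last_reset`, the latest of session start,
last tic and last reward. A reward falls due at exactly
`last_reset + dro_interval_ms` (closed right endpoint), and delivering it
restarts the countdown, so sustained suppression earns one reward per
interval. The alternative reading — a fixed 10-s grid that does not restart
at reward delivery — is indistinguishable during tic-free stretches; we
chose restart-at-reward because it generalizes the "time since the last
tic" rule uniformly to all resets. Two boundary rules follow:

* a tic landing at the exact due offset **pre-empts** the reward (events at
  equal offsets order tic before reward): an interval containing a tic is
  never rewarded;
* the pre-emption rule applies to DRZ only. NCR replays its source offsets
  exactly, so a source reward coinciding with a tic is still delivered,
  ordered after the tic.

A session ends when the planned duration elapses, when the rater ends it,
or when a connection is lost; the end-reason vocabulary is fixed to three
strings (`"duration elapsed"`, `"rater ended"`, `"connection closed"`) so
logs stay machine-parseable. NCR rewards scheduled beyond the session's end
are dropped silently and counted in the summary as undelivered.

```{r engine}
cfg <- session_config("DRZ", 300000, "au5")
rec <- run_session(cfg, tic_offsets = c(3000, 7000),
                   start_datetime = "2020-06-22 15:31:25")
head(rec$events)
rec$summary$reward_count
```

The engine's event sequences are verified in the test suite against an
independent brute-force oracle that steps the clock one millisecond at a
time, over randomized sessions of all four conditions.

## The lag-compensated check-in protocol

In remote operation the subject's reward display and the rater's tic marks
live on opposite sides of a network, with the session clock held by a
server. The display client cannot simply sleep until the next due time: it
does not know when the last tic was. Instead it checks in with the server,
which answers with the time remaining until the next reward is due; the
client re-polls after that remaining time minus half the measured round
trip (the one-way lag estimate under a symmetric link, see
`next_check_delay()`), and displays the reward at its compensated wake
moment. A tic signalled between the server's answer and the due time
cancels the pending delivery — the server is authoritative. Consecutive
polls are kept at least 10 ms apart to avoid a busy loop when the remaining
time is near zero.

`run_checkin_loop()` simulates this protocol by discrete events on a
virtual clock. Each check-in samples one round-trip time (RTT) from a
`lag_model()`; the forward and return legs split the RTT by an independent
uniform fraction. Because the remaining time is measured at the server in
mid-exchange while the client compensates with half the total round trip,
the delivery error of each reward is half the difference between the two
legs. Three consequences, all asserted in the tests:

* at zero lag, delivered offsets coincide exactly with the engine's reward
  offsets;
* at constant RTT, every absolute error is bounded by RTT/2;
* under RTT ~ uniform(20, 200) ms with Poisson tics at 6/min, the median
  absolute error is about 22 ms — comfortably within the 50 ms that remote
  reward delivery is expected to hold.

```{r lag}
tr <- run_checkin_loop(cfg, tic_offsets = numeric(0),
                       lag = lag_model("uniform", min_ms = 20, max_ms = 200),
                       seed = 1)
summary(abs(tr$error))
```

`compensate = FALSE` re-polls after the uncompensated remaining time, which
roughly doubles the typical error; the test suite checks the ordering over
100 seeded simulations.

## The `.ttsd` session log

Sessions are archived as plain text under
`<research_id>_<YYYYMMDD-HHMMSS>_<condition>.ttsd`; the research ID may not
contain underscores, so the name parses back unambiguously
(`parse_archive_filename()`). The file dialect, named `ttw-spec-1` in every
header, is: `key: value` header lines, one tab-separated line per event
(`offset<TAB>kind<TAB>detail`), then a summary block introduced by the
sentinel `=== summary ===`. Offsets inside the file are integer
milliseconds from session start.

`parse_ttsd()` re-sorts events defensively, recomputes the summary from the
event lines and rejects any disagreement with the embedded block, with a
line-numbered error. One field is special: an NCR log references its source
schedule by filename only, so `undelivered_reward_count` cannot be
recomputed from the events alone; the parser validates and carries the
embedded value. Serialization is deterministic byte-for-byte, and
`parse(serialize(record))` reproduces the record field for field — a
property asserted over randomized records of all four conditions.

## Session metrics

`summarize_session()` reports tic and reward counts, tics per minute
(normalized by the actual, possibly early-ended, duration), the mean
inter-tic interval (defined only with at least two tics), and the longest
tic-free interval, computed over gaps between consecutive tics plus the two
boundary gaps. `suppression_ratio()` divides a session's tic rate by the
baseline rate (values below 1 indicate suppression) and is `NA` when the
baseline rate is zero. `summary_table()` flattens records into one row per
session for TSV export.

## Simulated tic streams

`tic_stream_model()` generates synthetic tic streams so every module is
testable without human data: a Poisson process (exponential inter-tic
intervals) or a gamma renewal process (shape > 1 more regular, < 1
burstier), with a suppression multiplier in (0, 1] thinning the rate under
DRZ and verbal conditions. The default persona — 6 tics/min at baseline,
multiplier 0.3, gamma shape 2 — represents plausible magnitudes for a child
with a tic disorder and exists to exercise the machinery; it is not fitted
to any subject. `rater_latency_model()` additionally perturbs true tic
times by a nonnegative reaction latency, since the rater's keypress trails
the tic.

What the simulator does *not* emulate: tic clustering beyond what a renewal
process produces, rate drift within a session, reactive effects of rewards
on tic probability, or rater misses and false alarms. Passing tests
therefore demonstrate that the *machinery* (scheduling, logging, replay,
timing) is correct under controlled input, not that any behavioral claim
holds for real subjects.

Test problem sizes are the package's own choices: property suites run on
15–60 s sessions (where the 1-ms oracle is cheap), calibration checks use
1000 replicates at 300 s, and the timing acceptance check uses 50 seeded
300-s sessions.

## Command line

The installed script at `system.file("cli", "ttsd.R", package =
"ticsession")` exposes four subcommands — `run`, `simulate`, `replay`,
`summarize` — each archiving or reading `.ttsd` files through the package
functions; durations are given in seconds and stored as milliseconds, and a
`--config` file of `key value` lines can supply flag defaults. Live `run`
mode is a line-oriented adaptation: R has no portable raw-keypress terminal
loop, so "t"+Enter marks a tic, "e"+Enter ends the session, end-of-input
counts as a closed connection, and rewards are announced (with a terminal
bell) at check-in points rather than rendered audiovisually. For
precise-timing live use the check-in loop would be wired to a real
event-driven client; the simulation in `run_checkin_loop()` models exactly
that loop.

## Known limitations

* No network transport is included; `timing_sync` simulates the protocol
  on a virtual clock rather than speaking HTTP/WebSocket.
* Lag compensation assumes a symmetric link (one-way lag = RTT/2); clock
  skew beyond that is out of scope.
* Whether upstream session files from other implementations are
  byte-compatible with the `ttw-spec-1` dialect is unknown; the parser is
  versioned so other dialects can be added.
* The live CLI mode trades timing precision for portability, as described
  above.
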