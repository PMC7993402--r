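Package: ticsession
Title: Session Engine and Timing Simulation for the Tic Suppression Paradigm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Headless implementation of the tic suppression paradigm (TSP)
    session protocol used in tic-disorder research. Provides a deterministic
    session engine for the four experimental conditions (baseline, verbal
    instruction, differential reinforcement of zero-rate ticcing, and
    noncontingent reinforcement), a plain-text '.ttsd' session-log format with
    archival file naming, replay of archived reward schedules for the
    noncontingent condition, per-session summary metrics, synthetic tic-stream
    generation for testing, a discrete-event simulation of the lag-compensated
    client/server check-in protocol that schedules reward delivery, and a
    command-line interface for running, simulating, and summarizing sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
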