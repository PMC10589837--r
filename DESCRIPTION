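Package: drumtrainr
Title: Timing-Window Scoring and Gamified Progression for Tablet-Based
    Drumming Training
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless engine for a gamified rhythmic drumming training
    program used in sensorimotor rehabilitation. Generates the 22-session
    training catalog (paradiddle-based rhythm patterns on a monotone tempo
    ramp), derives target-beat timelines with tempo-dependent symmetric hit
    windows, scores tap-event logs against those timelines (per-beat binary
    accuracy and signed latency plus session summary statistics), drives the
    accuracy-threshold session-unlock state machine, quantifies training
    adherence against the prescribed weekly dose, and simulates virtual
    participants with controlled asynchrony, jitter, miss, extra-tap, and
    wrong-hand parameters. Target timelines round-trip through standard MIDI
    files; all logs and reports use plain CSV and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
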