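# drumtrainr

Headless engine for a gamified, tablet-based rhythmic drumming training
program used in sensorimotor rehabilitation (e.g. for people with
basal-ganglia disorders such as Huntington disease). The training app
plays 1 introduction plus 22 audio sessions of paradiddle-based rhythms on
two on-screen drums; participants drum along, and everything that matters
scientifically happens in the data layer underneath the GUI. This package
implements that layer as a standalone R library for researchers analysing
(or prototyping) such interventions:

* **Session catalog** — the 23-session program with its monotone tempo
  ramp (55 → 117 beats/min), paradiddle patterns (R L R R L R L L),
  non-decreasing target counts, and target-beat timelines read/written as
  standard MIDI files.
* **Scoring** — an accurate response is a correct-hand tap inside a
  symmetric window around the expected hit, with the total window width
  `w(t)` scaled to tempo `t` (beats/min):

  `w(t) = 1000 ms` for `t < 60`, `100 ms` for `t > 100`, linear in
  between; each target scores accuracy ∈ {0, 1} and signed latency
  (tap − onset, positive = late), summarised into the eight per-session
  statistics (mean/min latency and accuracy, overall and per hand).
* **Progression** — the unlock state machine: the first three sessions
  are open from the start, and from session 3 onward an accuracy ≥ 70%
  unlocks the next session.
* **Adherence** — weekly rollups of engagement logs against the
  prescribed dose (10–15 min/day, 5 sessions/week, 8 weeks).
* **Simulator** — a virtual tapper with mean asynchrony μ, timing jitter
  σ (tap times `N(onset + μ, σ)`), miss probability, Poisson extra-tap
  rate and wrong-hand probability, so the whole pipeline is testable
  end-to-end without participants.

## Worked example

Score a simulated participant on session 3 and feed the result to the
progression engine:

```r
library(drumtrainr)

cat22 <- default_catalog()
spec  <- catalog_session(cat22, 3)
profile <- tapper_profile(mean_asynchrony = 45, jitter_sd = 30,
                          miss_prob = 0.1, extra_rate = 0.2,
                          wrong_hand_prob = 0.05, seed = 42)
taps <- simulate_taps(build_timeline(spec), profile)
res  <- score_session(spec, taps)
res
#> <session_result> session 3: accuracy 91.7% over 48 targets, 13 extra taps
#>   mean latency +41.9 ms (window 887.5 ms)

upd <- apply_result(initial_state(cat22), 3L, res$summary$mean_accuracy)
upd$feedback
#> [1] "unlocked_next"
upd$state$unlocked
#> [1] 0 1 2 3 4
```

The participant hit 44 of 48 targets (91.7% ≥ 70%), tapping on average
41.9 ms late, so session 4 unlocks. The 13 extra taps (surplus,
wrong-drum, or outside every window) are logged with accuracy 0 but do
not dilute the accuracy denominator, which is always the number of
target beats.

A command-line wrapper covering the same pipeline
(`catalog`, `simulate`, `score`, `progress`, `report`) is installed as
`exec/drumtrainr`:

```sh
Rscript exec/drumtrainr catalog --summary
Rscript exec/drumtrainr simulate --session 3 --profile profile.json --out taps.csv
Rscript exec/drumtrainr score --session 3 --taps taps.csv --out session3.csv
```

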