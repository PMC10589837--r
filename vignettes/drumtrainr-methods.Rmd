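---
title: "Scoring, progression, and simulation methods in drumtrainr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, progression, and simulation methods in drumtrainr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drumtrainr)
```

## The problem

Rhythmic drumming training for people with basal-ganglia disorders pairs a
pre-recorded audio program with a tablet interface: two on-screen drums
(left triangle, high pitch; right circle, low pitch), a catalog of
sessions that grow in tempo and complexity, and a gamified unlock rule
that holds users at a difficulty matched to their ability. The tablet app
itself is a GUI; everything scientifically load-bearing underneath it —
what counts as an accurate tap, how windows scale with tempo, when a
session unlocks, how adherence is measured — is a deterministic
computation on event logs. `drumtrainr` implements that computation as a
standalone, testable library, plus a virtual-tapper simulator so the whole
pipeline can be exercised without human participants.

## The session catalog

The program is one introduction plus 22 training sessions. Published
constraints pin the endpoints: session 1 is a slow regular pulse below
one beat per second (all four beats, no metronome), the maximum tempo is
117 beats/min, tempo and target counts never decrease, sessions 1–7 are
practiced hand-by-hand before both hands, later sessions with both hands
and in reverse, and background tracks are shared by groups of three
consecutive sessions. Within those constraints the exact per-session
tempos and cycle counts are a design choice of this package: the default
ramp runs 55, 60, 65, …, 115, 117 beats/min, the first three sessions are
four-beat alternating pulses of 40/44/48 targets, and from session 4 the
patterns are eight-stroke paradiddles (R L R R L R L L, half-beat
spacing — the standard rudiment timing, since no note values are
published) whose cycle counts grow from 56 to 200 targets. Everything is
reconfigurable through a JSON catalog (`write_catalog_json()` /
`read_catalog_json()`), and `validate_catalog()` enforces the published
shape.

```{r}
head(catalog_summary(default_catalog())[, 1:7])
```

## Hit windows

An accurate response is a correct-hand tap inside a symmetric window
around the expected hit. The published schedule gives two anchors: a
1000 ms total window below 60 beats/min and 100 ms above 100 beats/min,
with a "gradual" reduction in between. We interpolate linearly in tempo
between (60, 1000) and (100, 100) — the simplest monotone schedule
consistent with both anchors — and hold the window constant outside that
range, so the width always lies in [100, 1000] ms.

At half-beat stroke spacing a fast pattern's inter-onset interval can be
smaller than the scheduled window. To keep per-beat scoring well defined,
`build_timeline()` clamps every half-window to 45% of the smaller
adjacent inter-onset interval. The 45% figure leaves a 10% guard band
between neighbouring windows, guaranteeing pairwise disjoint windows and
hence a unique owning target for any tap; the timeline constructor
re-checks disjointness and refuses overlapping input.

## Matching and summary statistics

`match_taps()` sorts taps stably by timestamp and, for each target, picks
among the correct-drum taps inside its window the one with the smallest
absolute latency, breaking ties toward the earlier tap (a deterministic
choice; signed latency is tap minus onset, positive = late, the usual
sensorimotor-synchronization convention). Because windows are disjoint,
each tap is eligible for at most one target, so this greedy pass is
provably equivalent to an exhaustive search over one-to-one assignments
maximizing hit count then minimizing total absolute latency — the test
suite verifies that equivalence against an independent brute-force oracle
on a thousand random small instances.

Every input tap is classified exactly once: matched, `surplus_in_window`
(correct drum, window already served), `wrong_drum_in_window`, or
`outside_all_windows`. Accuracy is the fraction of *target beats* scored
1 — extra taps are logged with accuracy 0 but never enter the
denominator, which keeps accuracy in [0, 1] and ties it to the "total
number of target beats" metadatum. A wrong-drum tap does not rescue its
target. When both drums could in principle carry simultaneous targets the
per-target decision would become ambiguous; the default catalog never
schedules simultaneous targets, and the timeline constructor's
disjointness requirement makes the assumption explicit.

The per-session summary holds the eight statistics logged by the app:
mean latency and mean accuracy overall and per hand, and the minimum
(best) absolute latency per hand. Latency statistics are computed over
accurate taps only and are missing — empty CSV fields, never 0 or a
sentinel — when no accurate tap exists, so an all-miss session cannot
corrupt downstream means.

## Progression

The unlock state machine starts with the introduction and the first three
training sessions available. From session 3 onward, an accuracy of at
least the threshold (0.70 by default) unlocks exactly the next session;
the comparison is `>=` on the exact fraction, with no rounding (0.695
does not unlock). Sessions 1 and 2 always report "completed" because
their successors are pre-unlocked; we apply the same rule to session 22,
which has no successor. The unlocked set never shrinks, replays can only
improve the recorded best accuracy, and the engine imposes no forced
repetition — the advice to repeat a failed session is UI text, not a
mechanism. State serialises to JSON losslessly.

## Adherence

The prescribed dose is 10–15 minutes per day, 5 sessions per week, for
8 weeks. `adherence_summary()` rolls an engagement log (16-character
tablet code, session index, ISO 8601 start, duration) into weekly counts
and minutes using rolling 7-day windows anchored at the first engagement:
a home program starts on an arbitrary weekday, so calendar or ISO weeks
would split a prescribed week across two bins. The adherence fraction is
attended over planned sessions (5 × 8 = 40) and is reported as computed,
not clipped at 1; "5 times/wk" is counted as sessions, not distinct days.
No personal identifiers appear anywhere in the records.

## The virtual tapper

`simulate_taps()` draws one performance of a timeline under the standard
sensorimotor-synchronization noise model: each target is produced with
probability `1 - miss_prob`, at onset plus a Gaussian asynchrony
`N(mean_asynchrony, jitter_sd)` (milliseconds), on the wrong drum with
probability `wrong_hand_prob`; unrelated extra taps arrive as a
homogeneous Poisson stream at `extra_rate` per second. A single RNG
stream per simulation makes every run reproducible from the profile seed.

On a single-hand, shared-window timeline the expected accuracy has the
closed form

$$(1-p_{miss})\,(1-p_{wrong})\;P\!\left(|N(\mu,\sigma)| \le w/2\right),$$

and the latency distribution of accurate taps is the normal truncated to
the window. Both are checked in the tests (Monte-Carlo comparison over
100 seeds; Kolmogorov–Smirnov at n = 10,000, alpha = 0.01). On mixed-hand
timelines a wrong-drum tap can occasionally land in a neighbouring
opposite-hand window and be matched there, so the closed form is a slight
underestimate; the validation therefore uses single-hand timelines.

What the simulator emulates — stationary Gaussian timing noise with
independent misses — is deliberately simpler than real participants:
there is no learning curve, no drift or tempo-coupled variance, no
perseverative tap bursts, and no touch-hardware latency. Passing tests
demonstrate that the *engine* is correct under a known generative model,
not that the model captures patient behaviour.

## Numerical and format choices

* Target onsets are integer milliseconds; tap timestamps are kept as
  doubles end to end (rounding simulated taps to a 1 ms grid would
  create ties that bias the distributional checks, for no gain).
* MIDI timelines are format-0 files, PPQ 480, with the tempo meta-event
  fixed at 480,000 µs per quarter note so one tick is exactly one
  millisecond — onsets round-trip bit-exactly at any session tempo,
  which a session-tempo tick clock cannot guarantee at slow tempos.
  The session tempo travels in a JSON sidecar, from which half-windows
  (not representable in MIDI) are reconstructed on read. Left = note 60,
  right = note 45; any other note number is a format error.
* Output files are RFC 4180 CSV, UTF-8, ISO 8601 timestamps, empty
  fields for missing values, and round-trip the scored session exactly
  (numbers printed with 17 significant digits).

## Problem sizes in the checks

The test suite and the reproduction script use 200-target timelines for
parameter recovery (standard error 20/√200 ≈ 1.4 ms), 100 seeds ×
200 targets for the accuracy closed form (Monte-Carlo SE ≈ 0.3
percentage points), 1000 random ≤ 6×6 instances for the exhaustive-search
comparison, and 10,000 taps for the distributional check — sizes at which
the sampling error of each check is an order of magnitude below the
effect it guards.

## Known limitations

* The catalog's interior (exact tempos, cycle counts, styles beyond the
  four named) is this package's documented choice, not a published fact.
* Scoring is batch, not streaming; hardware touch latency is out of
  scope and would shift mean latency additively.
* The metronome/high-hat sounds are not represented in the scoring
  reference and never scored.
* Whether a wrong-drum tap should count against a simultaneous
  opposite-hand window is undefined here because simultaneous targets
  are excluded by construction.
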