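# Shared fixtures: random scoring instances and an exhaustive-search
# matching oracle, kept independent of the greedy matcher it checks.

# random timeline with guaranteed-disjoint windows (half-window at most
# 45% of the smaller adjacent gap, mirroring the production clamp)
random_timeline <- function(n_targets, min_gap = 200, max_gap = 1200) {
  if (n_targets == 0) {
    return(target_timeline(1L, numeric(0), character(0), numeric(0)))
  }
  gaps <- round(runif(n_targets, min_gap, max_gap))
  onsets <- cumsum(gaps)
  adj <- pmin(c(gaps[-1], Inf), c(Inf, gaps[-1]))
  adj <- pmin(adj, c(gaps[1], rep(Inf, n_targets - 1)))
  # conservative bound: 45% of the smallest gap touching each target
  lo_gap <- c(gaps[1], diff(onsets))
  hi_gap <- c(diff(onsets), Inf)
  hw <- pmin(runif(n_targets, 50, 500), 0.45 * pmin(lo_gap, hi_gap))
  target_timeline(1L, onsets, sample(hand_sides(), n_targets,
                                     replace = TRUE), hw)
}

random_taps <- function(n_taps, span_ms) {
  tap_events(runif(n_taps, 0, span_ms),
             sample(hand_sides(), n_taps, replace = TRUE))
}

# exhaustive search over all one-to-one tap -> target assignments,
# maximizing (# accurate matches, then -sum |latency| of those matches)
oracle_match <- function(timeline, taps) {
  b <- timeline$beats
  n_t <- nrow(b)
  ord <- order(taps$timestamp_ms)
  ts <- taps$timestamp_ms[ord]
  drum <- taps$drum[ord]
  n_p <- length(ts)
  eligible <- function(j, i) {
    drum[i] == b$hand[j] && abs(ts[i] - b$onset_ms[j]) <= b$half_window_ms[j]
  }
  best <- list(n_acc = -1L, sum_lat = Inf, assign = rep(NA_integer_, n_t))
  recurse <- function(j, used, assign, n_acc, sum_lat) {
    if (j > n_t) {
      if (n_acc > best$n_acc ||
          (n_acc == best$n_acc && sum_lat < best$sum_lat - 1e-9)) {
        best <<- list(n_acc = n_acc, sum_lat = sum_lat, assign = assign)
      }
      return(invisible())
    }
    recurse(j + 1L, used, assign, n_acc, sum_lat)   # leave target unmatched
    for (i in seq_len(n_p)) {
      if (!used[i] && eligible(j, i)) {
        used[i] <- TRUE
        assign[j] <- i
        recurse(j + 1L, used, assign, n_acc + 1L,
                sum_lat + abs(ts[i] - b$onset_ms[j]))
        used[i] <- FALSE
        assign[j] <- NA_integer_
      }
    }
  }
  recurse(1L, rep(FALSE, n_p), rep(NA_integer_, n_t), 0L, 0)
  accuracy <- as.integer(!is.na(best$assign))
  latency <- rep(NA_real_, n_t)
  hit <- which(accuracy == 1L)
  latency[hit] <- ts[best$assign[hit]] - b$onset_ms[hit]
  list(accuracy = accuracy, latency = latency, n_accurate = best$n_acc)
}

# small deterministic two-target instance used across scoring tests
two_target_instance <- function() {
  list(
    timeline = target_timeline(1L, c(1000, 2000), c("left", "left"),
                               c(450, 450)),
    taps = tap_events(c(1100, 2600), c("left", "left"))
  )
}
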