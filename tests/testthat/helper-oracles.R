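# Independent oracles used to cross-check the implementation.

# Brute-force interval-algorithm burst detector: enumerates every contiguous
# spike subsequence O(n^3), keeps those that are maximal runs under the
# intra-burst ISI bound, merges neighbours below the inter-burst gap to a
# fixpoint, then filters on count and span. Deliberately structured unlike
# detect_bursts() (which splits on diff() breakpoints in one pass).
oracle_bursts <- function(ts, params = burst_params()) {
  n <- length(ts)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), duration = numeric(0))
  if (n == 0L) return(empty)
  segs <- list()
  for (i in 1:n) for (j in i:n) {
    run_ok <- j == i || all(diff(ts[i:j]) <= params$max_intra_isi)
    left_maximal <- i == 1L || ts[i] - ts[i - 1L] > params$max_intra_isi
    right_maximal <- j == n || ts[j + 1L] - ts[j] > params$max_intra_isi
    if (run_ok && left_maximal && right_maximal)
      segs[[length(segs) + 1L]] <- c(i, j)
  }
  segs <- segs[order(vapply(segs, `[`, 0, 1L))]
  repeat {
    merged_any <- FALSE
    k <- 1L
    while (k < length(segs)) {
      if (ts[segs[[k + 1L]][1L]] - ts[segs[[k]][2L]] < params$min_interburst) {
        segs[[k]] <- c(segs[[k]][1L], segs[[k + 1L]][2L])
        segs[[k + 1L]] <- NULL
        merged_any <- TRUE
      } else k <- k + 1L
    }
    if (!merged_any) break
  }
  rows <- Filter(function(s) {
    (s[2L] - s[1L] + 1L) >= params$min_spikes &&
      (ts[s[2L]] - ts[s[1L]]) >= params$min_duration
  }, segs)
  if (!length(rows)) return(empty)
  data.frame(start = vapply(rows, function(s) ts[s[1L]], 0),
             end = vapply(rows, function(s) ts[s[2L]], 0),
             n_spikes = vapply(rows, function(s) s[2L] - s[1L] + 1L, 0L),
             duration = vapply(rows, function(s) ts[s[2L]] - ts[s[1L]], 0))
}

# OR-of-squares oracle for biomimetic pulse merging: rasterize one square per
# spike on a fine grid, OR them, and read the on-runs back off the grid.
# Spike times aligned to the grid make the comparison exact.
oracle_or_of_squares <- function(ts, duration, pulse_width = 0.003,
                                 rate = 10000) {
  n <- round(duration * rate)
  s <- numeric(n)
  for (t in ts) {
    i0 <- ceiling(t * rate - 1e-9)
    i1 <- ceiling(min(t + pulse_width, duration) * rate - 1e-9) - 1
    if (i1 >= i0 && i0 < n) s[(i0 + 1):(min(i1, n - 1) + 1)] <- 1
  }
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  on <- runs$values == 1
  list(onset = starts[on] / rate, offset = ends[on] / rate)
}

# Random grid-aligned spike train (distinct timestamps, multiples of `grid`).
random_grid_train <- function(n, duration, grid = 1e-4, condition = "morphine") {
  slots <- sort(sample.int(round(duration / grid) - 1L, n))
  spike_train(slots * grid, duration = duration, condition = condition)
}

# Random valid pulse schedule with edges on a 1e-4 s grid.
random_schedule <- function(n, total = 2) {
  slots <- sort(sample.int(round(total / 1e-4) - 1L, 2L * n))
  pulse_schedule(slots[c(TRUE, FALSE)] * 1e-4, slots[c(FALSE, TRUE)] * 1e-4,
                 total_duration = total)
}
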