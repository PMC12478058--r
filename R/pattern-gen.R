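#' Biomimetic stimulation pattern from a spike train
#'
#' Converts the temporal occurrences of action potentials into binary laser
#' pulse-triggering events: one fixed-width pulse `[t, t + pulse_width)` per
#' spike at time `t`, so the light pulses directly mirror the position of
#' each spike in the source recording. When an ISI is shorter than the pulse
#' width the overlapping pulses are merged into a single on-interval — the
#' behavior of a laser driven by OR-ed trigger pulses — and the merge count
#' is recorded in the annotation.
#'
#' @param train A [spike_train].
#' @param pulse_width Pulse width in seconds (default 0.003; 3 ms pulses
#'   suit fast channelrhodopsin variants).
#' @return A [pulse_schedule] with `total_duration = train$duration` and
#'   annotation fields `pattern_mode = "biomimetic"`, `source_unit`,
#'   `source_condition`, `n_merged`.
#' @export
biomimetic_pattern <- function(train, pulse_width = 0.003) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.numeric(pulse_width) || pulse_width <= 0)
    stop("`pulse_width` must be positive", call. = FALSE)
  ts <- train$timestamps
  ann <- list(pattern_mode = "biomimetic", source_unit = train$unit_id,
              source_condition = train$condition, n_merged = 0L)
  if (!length(ts))
    return(pulse_schedule(numeric(0), numeric(0), train$duration,
                          pulse_width = pulse_width, annotation = ann))
  ts <- ts[ts < train$duration]      # a spike at the segment end has no room for a pulse
  if (!length(ts))
    return(pulse_schedule(numeric(0), numeric(0), train$duration,
                          pulse_width = pulse_width, annotation = ann))
  on <- ts
  off <- pmin(ts + pulse_width, train$duration)
  # merge pulses that overlap or exactly touch the running offset: OR-ed
  # trigger pulses with no gap drive one continuous light interval
  m_on <- on[1L]; m_off <- off[1L]
  res_on <- numeric(0); res_off <- numeric(0); merged <- 0L
  if (length(on) > 1L) {
    for (k in 2:length(on)) {
      if (on[k] <= m_off + 1e-9) {   # 1 ns slack: addition noise, far below the 1 us grid
        m_off <- max(m_off, off[k]); merged <- merged + 1L
      } else {
        res_on <- c(res_on, m_on); res_off <- c(res_off, m_off)
        m_on <- on[k]; m_off <- off[k]
      }
    }
  }
  res_on <- c(res_on, m_on); res_off <- c(res_off, m_off)
  ann$n_merged <- merged
  pulse_schedule(res_on, res_off, train$duration,
                 pulse_width = pulse_width, annotation = ann)
}

#' ISI-shuffled surrogate of a spike train
#'
#' Preserves the interspike intervals themselves while re-arranging their
#' temporal order relative to one another, destroying any repeating
#' sequences or higher-order arrangement of intervals. The first spike time
#' is kept fixed (the initial latency is not an ISI) and the sequence of
#' ISIs after it is replaced by a uniformly random permutation drawn from
#' the given seed, so spike count, first/last spike times, total span, ISI
#' multiset, and mean rate are all conserved while interval order is not.
#'
#' @param train A [spike_train] with at least 3 spikes (2 ISIs), the
#'   smallest train with a non-trivial permutation.
#' @param seed Integer seed; the same train and seed always regenerate the
#'   identical surrogate (Mersenne-Twister, recorded in the provenance).
#' @return A [spike_train] with `condition = "shuffled"` and a `provenance`
#'   attribute `(source_unit, source_condition, seed, rng)`.
#' @export
shuffle_isis <- function(train, seed) {
  stopifnot(inherits(train, "spike_train"))
  ts <- train$timestamps
  if (length(ts) < 3L)
    stop("need >= 3 spikes (2 ISIs) for a non-trivial shuffle", call. = FALSE)
  isis <- diff(ts)
  perm <- with_seed(seed, sample.int(length(isis)))
  new_ts <- c(ts[1L], ts[1L] + cumsum(isis[perm]))
  # permuted float sums can land epsilon past the segment end
  out <- spike_train(pmin(new_ts, train$duration), duration = train$duration,
                     unit_id = train$unit_id, condition = "shuffled",
                     dose_mg_per_kg = train$dose_mg_per_kg,
                     subject_id = train$subject_id)
  attr(out, "provenance") <- list(source_unit = train$unit_id,
                                  source_condition = train$condition,
                                  seed = as.integer(seed),
                                  rng = "Mersenne-Twister")
  out
}

#' Mean firing rate of a spike train
#'
#' Spike count over the full segment duration (not span between first and
#' last spike), matching the per-condition rate convention on fixed-length
#' segments; identical to [baseline_rate()] but without the
#' baseline-condition warning, for use on any condition.
#'
#' @param train A [spike_train].
#' @return Rate in spikes/s.
#' @export
mean_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (train$duration <= 0) stop("zero-duration segment", call. = FALSE)
  length(train$timestamps) / train$duration
}

#' Frequency-matched tonic stimulation pattern
#'
#' Evenly spaced pulses at a fixed rate — the rate-coding control: a tonic
#' file matched to a recorded pattern's average firing rate carries its
#' frequency but none of its temporal structure. Pulses start at `t = 0`
#' (phase is irrelevant to a frequency-matched control) and number
#' `floor(rate * total_duration)`.
#'
#' @param rate Pulse rate in spikes/s; must satisfy
#'   `0 < rate <= 1 / pulse_width` so consecutive pulses never overlap.
#' @param total_duration Schedule length in seconds.
#' @param pulse_width Pulse width in seconds (default 0.003).
#' @return A [pulse_schedule] with `pattern_mode = "tonic"` and
#'   `matched_rate_hz` in the annotation.
#' @export
tonic_pattern <- function(rate, total_duration, pulse_width = 0.003) {
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be positive", call. = FALSE)
  if (rate > 1 / pulse_width)
    stop(sprintf("rate %g Hz gives period %.4g s shorter than the %.4g s pulse width: pulses would overlap",
                 rate, 1 / rate, pulse_width), call. = FALSE)
  count <- floor(rate * total_duration + 1e-9)
  on <- if (count >= 1) (seq_len(count) - 1) / rate else numeric(0)
  off <- pmin(on + pulse_width, total_duration)
  pulse_schedule(on, off, total_duration, pulse_width = pulse_width,
                 annotation = list(pattern_mode = "tonic",
                                   matched_rate_hz = rate))
}

#' Continuous duty-cycle stimulation pattern
#'
#' Unpulsed light delivered in long repeating phases, by default 30 s on
#' then 60 s off, cycling from `t = 0` and clipped to the schedule length.
#'
#' @param on_duration Light-on phase length in seconds (default 30).
#' @param off_duration Light-off phase length in seconds (default 60).
#' @param total_duration Schedule length in seconds.
#' @return A [pulse_schedule] with `pattern_mode = "continuous"`; the
#'   schedule's `pulse_width` is the on-phase duration.
#' @export
continuous_pattern <- function(total_duration, on_duration = 30,
                               off_duration = 60) {
  if (on_duration <= 0 || off_duration <= 0)
    stop("phase durations must be positive", call. = FALSE)
  if (total_duration < 0) stop("`total_duration` must be >= 0", call. = FALSE)
  cycle <- on_duration + off_duration
  k <- 0:max(0, ceiling(total_duration / cycle))
  on <- k * cycle
  keep <- on < total_duration
  on <- on[keep]
  off <- pmin(on + on_duration, total_duration)
  pulse_schedule(on, off, total_duration, pulse_width = on_duration,
                 annotation = list(pattern_mode = "continuous",
                                   on_s = on_duration, off_s = off_duration))
}
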