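#' Simulate an irregular spike train
#'
#' Gamma-renewal interspike intervals with an absolute refractory floor:
#' each ISI is `refractory + X` where `X ~ Gamma(shape = 1/isi_cv^2)` scaled
#' so the mean ISI is exactly `1 / mean_rate`. A two-parameter renewal
#' family reproduces rate and irregularity independently, which a Poisson
#' process cannot; `isi_cv = 1` gives exponential-like irregular firing of
#' the kind seen in fast-firing midbrain GABA units. Optional burst
#' injection overlays dense spike runs (a Poisson event process, each event
#' a run of spikes at short uniform ISIs) on the background train. The
#' result is sorted, refractory-deduplicated, and clipped to the segment.
#'
#' @param mean_rate Target mean firing rate, spikes/s.
#' @param duration Segment length in seconds.
#' @param isi_cv Coefficient of variation of the gamma component
#'   (shape = `1/isi_cv^2`). Default 1.
#' @param refractory Absolute refractory period in seconds (default 0.002);
#'   must be smaller than the mean ISI `1/mean_rate`.
#' @param seed Integer seed; identical configurations and seeds reproduce
#'   identical trains.
#' @param bursts Optional list with `events_per_s` (burst event rate),
#'   `spikes_per_burst` (integer range, default `c(4, 8)`), and
#'   `intra_isi` (ISI range in seconds inside a burst, default
#'   `c(0.004, 0.008)`). Defaults satisfy the standard four burst criteria
#'   with margin, so injected bursts are detectable by design.
#' @param unit_id,condition,dose_mg_per_kg,subject_id Metadata passed to
#'   [spike_train()].
#' @return A [spike_train] with a `sim_config` attribute recording all
#'   parameters and the seed.
#' @export
simulate_train <- function(mean_rate, duration, isi_cv = 1,
                           refractory = 0.002, seed = NULL, bursts = NULL,
                           unit_id = "sim", condition = "baseline",
                           dose_mg_per_kg = NULL, subject_id = NULL) {
  if (mean_rate <= 0 || duration <= 0 || isi_cv <= 0 || refractory < 0)
    stop("rates, durations, and cv must be positive; refractory >= 0",
         call. = FALSE)
  mu <- 1 / mean_rate
  if (refractory >= mu)
    stop(sprintf("infeasible: refractory %.4g s >= mean ISI %.4g s",
                 refractory, mu), call. = FALSE)
  shape <- 1 / isi_cv^2
  scale <- (mu - refractory) / shape
  ts <- with_seed(seed, {
    target <- ceiling(mean_rate * duration * 1.25 + 50)
    isis <- refractory + stats::rgamma(target, shape = shape, scale = scale)
    t <- cumsum(isis)
    while (t[length(t)] < duration) {
      extra <- refractory + stats::rgamma(target, shape = shape, scale = scale)
      t <- c(t, t[length(t)] + cumsum(extra))
    }
    t <- t[t <= duration]
    if (!is.null(bursts)) {
      spb <- if (is.null(bursts$spikes_per_burst)) c(4L, 8L) else bursts$spikes_per_burst
      iri <- if (is.null(bursts$intra_isi)) c(0.004, 0.008) else bursts$intra_isi
      n_ev <- stats::rpois(1L, bursts$events_per_s * duration)
      if (n_ev > 0L) {
        starts <- sort(stats::runif(n_ev, 0, duration))
        for (t0 in starts) {
          nb <- sample(spb[1L]:spb[2L], 1L)
          t <- c(t, t0 + cumsum(c(0, stats::runif(nb - 1L, iri[1L], iri[2L]))))
        }
        t <- sort(t[t <= duration])
      }
    }
    # enforce the refractory floor after overlaying bursts on background
    if (length(t) > 1L) {
      keep <- logical(length(t)); keep[1L] <- TRUE; last <- t[1L]
      for (i in 2:length(t)) {
        if (t[i] - last >= refractory) { keep[i] <- TRUE; last <- t[i] }
      }
      t <- t[keep]
    }
    t
  })
  out <- spike_train(ts, duration = duration, unit_id = unit_id,
                     condition = condition, dose_mg_per_kg = dose_mg_per_kg,
                     subject_id = subject_id)
  attr(out, "sim_config") <- list(mean_rate = mean_rate, duration = duration,
                                  isi_cv = isi_cv, refractory = refractory,
                                  seed = seed, bursts = bursts)
  out
}

#' Simulate a biphasic unit waveform
#'
#' A positive-then-negative biphasic template built from two disjoint raised
#' cosine lobes, so that in the noiseless case the global peak and trough
#' sit exactly `round(peak_to_trough * sample_rate)` samples apart and
#' [peak_to_trough()] recovers the configured value exactly (the
#' generator/analyzer closed loop). Gaussian noise, if requested, is added
#' after the template is built.
#'
#' @param peak_to_trough Target peak-to-trough time in seconds; must span at
#'   least one sample at `sample_rate`.
#' @param sample_rate Sampling rate in Hz (default 30000).
#' @param amplitude_ratio Peak amplitude over trough magnitude (default 1.5,
#'   a typical extracellular asymmetry).
#' @param noise_sd Noise standard deviation as a fraction of the peak
#'   amplitude (default 0).
#' @param seed Integer seed for the noise.
#' @param unit_id Metadata passed to [unit_waveform()].
#' @return A [unit_waveform] with a `sim_config` attribute.
#' @export
simulate_waveform <- function(peak_to_trough, sample_rate = 30000,
                              amplitude_ratio = 1.5, noise_sd = 0,
                              seed = NULL, unit_id = "sim") {
  k <- round(peak_to_trough * sample_rate)
  if (k < 1)
    stop(sprintf("peak_to_trough %.4g s is below one sample at %g Hz",
                 peak_to_trough, sample_rate), call. = FALSE)
  if (amplitude_ratio <= 0) stop("`amplitude_ratio` must be positive", call. = FALSE)
  h <- max(0L, floor((k - 1) / 2))       # lobe half-width; 2h < k keeps lobes disjoint
  lobe <- function(center, half, amp, n) {
    i <- seq_len(n) - 1L
    v <- numeric(n)
    idx <- abs(i - center) <= half
    v[idx] <- amp * (0.5 + 0.5 * cos(pi * (i[idx] - center) / (half + 1)))
    v
  }
  lead <- h + 4L
  n <- max(8L, lead + k + h + 5L)
  p <- lead
  s <- lobe(p, h, 1, n) - lobe(p + k, h, 1 / amplitude_ratio, n)
  if (noise_sd > 0)
    s <- s + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  out <- unit_waveform(s, sample_rate = sample_rate, unit_id = unit_id)
  attr(out, "sim_config") <- list(peak_to_trough = peak_to_trough,
                                  sample_rate = sample_rate,
                                  amplitude_ratio = amplitude_ratio,
                                  noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a compartment occupancy trace
#'
#' A two-state renewal model of side occupancy: dwell times are exponential
#' with mean `2 * bias * mean_dwell` on the paired side and
#' `2 * (1 - bias) * mean_dwell` outside, so the long-run paired-side
#' fraction converges to `bias` while the overall mean dwell stays
#' `mean_dwell`. The initial side is drawn with probability `bias`. This is
#' deliberately the simplest occupancy model that exposes a controllable
#' preference; it makes no claim about animal behavior.
#'
#' @param bias Long-run probability of being on the paired side, in (0, 1).
#' @param mean_dwell Overall mean dwell time per visit, seconds.
#' @param session_length Session length in seconds.
#' @param seed Integer seed.
#' @return An [occupancy_trace] with a `sim_config` attribute.
#' @export
simulate_occupancy <- function(bias = 0.5, mean_dwell = 30,
                               session_length = 1200, seed = NULL) {
  if (bias <= 0 || bias >= 1) stop("`bias` must be in (0, 1)", call. = FALSE)
  if (mean_dwell <= 0 || session_length <= 0)
    stop("dwell and session length must be positive", call. = FALSE)
  means <- c(in_paired = 2 * bias * mean_dwell,
             out = 2 * (1 - bias) * mean_dwell)
  trace <- with_seed(seed, {
    state <- if (stats::runif(1L) < bias) "in_paired" else "out"
    times <- 0; states <- state; t <- 0
    repeat {
      t <- t + stats::rexp(1L, 1 / means[[state]])
      if (t >= session_length) break
      state <- if (state == "in_paired") "out" else "in_paired"
      times <- c(times, t); states <- c(states, state)
    }
    occupancy_trace(times, states, session_length)
  })
  attr(trace, "sim_config") <- list(bias = bias, mean_dwell = mean_dwell,
                                    session_length = session_length,
                                    seed = seed)
  trace
}

#' Study-like spike-train configurations
#'
#' Named simulator configurations emulating the three source recordings the
#' stimulation patterns are built from: a morphine-condition train at
#' 18.8 Hz (pattern #1), a morphine-condition train at 22.2 Hz with sparse
#' bursts (pattern #2, the only source unit showing burst epochs), and a
#' drug-free baseline train at 16.7 Hz. Each is a 15-minute (900 s)
#' segment, matching the recording length used per condition.
#'
#' @return A named list of argument lists for [simulate_train()].
#' @export
study_train_configs <- function() {
  list(
    morphine_1 = list(mean_rate = 18.8, duration = 900, isi_cv = 1,
                      condition = "morphine", dose_mg_per_kg = 5,
                      unit_id = "cell1"),
    morphine_2 = list(mean_rate = 22.2, duration = 900, isi_cv = 1,
                      condition = "morphine", dose_mg_per_kg = 15,
                      unit_id = "cell2",
                      bursts = list(events_per_s = 0.05,
                                    spikes_per_burst = c(4L, 8L),
                                    intra_isi = c(0.004, 0.008))),
    baseline = list(mean_rate = 16.7, duration = 900, isi_cv = 1,
                    condition = "baseline", unit_id = "cell1")
  )
}
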