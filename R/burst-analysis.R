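#' Four-parameter interval-algorithm burst criteria
#'
#' Bursts are defined jointly by a maximum interspike interval inside a
#' burst, a minimum number of spikes, a minimum separation between bursts,
#' and a minimum burst duration. Defaults are the conventional interval
#' algorithm settings: 10 ms maximum intra-burst ISI, 4 spikes, 10 ms
#' inter-burst gap, 20 ms duration.
#'
#' @param max_intra_isi Maximum ISI between spikes within a burst (s).
#' @param min_spikes Minimum spikes per burst (at least 2).
#' @param min_interburst Minimum separation between bursts (s); candidate
#'   runs closer than this are merged before filtering.
#' @param min_duration Minimum first-to-last-spike span of a burst (s).
#' @return An object of class `burst_params`.
#' @export
burst_params <- function(max_intra_isi = 0.010, min_spikes = 4,
                         min_interburst = 0.010, min_duration = 0.020) {
  if (max_intra_isi <= 0 || min_interburst <= 0 || min_duration <= 0)
    stop("interval parameters must be positive", call. = FALSE)
  if (min_spikes < 2) stop("`min_spikes` must be >= 2", call. = FALSE)
  structure(list(max_intra_isi = max_intra_isi,
                 min_spikes = as.integer(min_spikes),
                 min_interburst = min_interburst,
                 min_duration = min_duration),
            class = "burst_params")
}

#' Detect bursts with the interval algorithm
#'
#' The detection pipeline is fixed as segment, then merge, then filter:
#' \enumerate{
#'   \item segment the train into maximal runs whose consecutive ISIs are
#'     all `<= max_intra_isi`;
#'   \item merge adjacent runs whose gap (first spike of the next minus last
#'     spike of the previous) is `< min_interburst`, cascading left to right;
#'   \item discard merged candidates with fewer than `min_spikes` spikes or a
#'     first-to-last span below `min_duration`.
#' }
#' Comparison senses read the maximum/minimum wording literally: intra-burst
#' ISIs inclusive of the maximum, spike count and duration inclusive of
#' their minima, merging strictly below the inter-burst minimum. Surviving
#' bursts are disjoint, ordered, and pairwise separated by at least
#' `min_interburst`.
#'
#' @param train A [spike_train], or a numeric vector of sorted timestamps.
#' @param params A [burst_params].
#' @return A data frame of class `burst_set` with columns `start`, `end`,
#'   `n_spikes`, `duration`, plus the index range of member spikes
#'   (`first_idx`, `last_idx`). Zero rows when no burst is found.
#' @export
detect_bursts <- function(train, params = burst_params()) {
  ts <- if (inherits(train, "spike_train")) train$timestamps else as.numeric(train)
  stopifnot(inherits(params, "burst_params"))
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), duration = numeric(0),
                      first_idx = integer(0), last_idx = integer(0))
  out_attr <- function(df) {
    class(df) <- c("burst_set", "data.frame")
    attr(df, "params") <- params
    attr(df, "train_signature") <- .train_signature(ts)
    df
  }
  n <- length(ts)
  if (n == 0L) return(out_attr(empty))
  # 1. maximal runs of ISIs <= max_intra_isi
  brk <- which(diff(ts) > params$max_intra_isi)
  first <- c(1L, brk + 1L)
  last <- c(brk, n)
  # 2. cascade-merge runs separated by < min_interburst
  m_first <- first[1L]; m_last <- last[1L]
  mf <- integer(0); ml <- integer(0)
  if (length(first) > 1L) {
    for (k in 2:length(first)) {
      if (ts[first[k]] - ts[m_last] < params$min_interburst) {
        m_last <- last[k]
      } else {
        mf <- c(mf, m_first); ml <- c(ml, m_last)
        m_first <- first[k]; m_last <- last[k]
      }
    }
  }
  mf <- c(mf, m_first); ml <- c(ml, m_last)
  # 3. filter on count and span
  n_sp <- ml - mf + 1L
  dur <- ts[ml] - ts[mf]
  keep <- n_sp >= params$min_spikes & dur >= params$min_duration
  out_attr(data.frame(start = ts[mf][keep], end = ts[ml][keep],
                      n_spikes = n_sp[keep], duration = dur[keep],
                      first_idx = mf[keep], last_idx = ml[keep]))
}

.train_signature <- function(ts) c(length(ts), sum(ts))

#' Summarize detected bursts
#'
#' Counts, burst rate over the segment, fraction of all spikes that fall in
#' bursts, and the mean intra-burst ISI — the summary quantities behind
#' burst raster figures.
#'
#' @param bursts A `burst_set` from [detect_bursts()].
#' @param train The same [spike_train] the bursts were detected on.
#' @return A list with `n_bursts`, `burst_rate_hz`, `fraction_spikes_in_bursts`,
#'   `mean_intra_burst_isi_s` (NA when there are no bursts), and
#'   `mean_spikes_per_burst`.
#' @export
burst_summary <- function(bursts, train) {
  stopifnot(inherits(bursts, "burst_set"), inherits(train, "spike_train"))
  sig <- attr(bursts, "train_signature")
  if (!isTRUE(all.equal(sig, .train_signature(train$timestamps))))
    stop("`bursts` were not detected on this train", call. = FALSE)
  ts <- train$timestamps
  n_b <- nrow(bursts)
  if (n_b == 0L)
    return(list(n_bursts = 0L, burst_rate_hz = 0,
                fraction_spikes_in_bursts = 0,
                mean_intra_burst_isi_s = NA_real_,
                mean_spikes_per_burst = 0))
  in_burst <- sum(bursts$n_spikes)
  isis <- unlist(lapply(seq_len(n_b), function(k)
    diff(ts[bursts$first_idx[k]:bursts$last_idx[k]])))
  list(n_bursts = n_b,
       burst_rate_hz = n_b / train$duration,
       fraction_spikes_in_bursts = in_burst / length(ts),
       mean_intra_burst_isi_s = mean(isis),
       mean_spikes_per_burst = in_burst / n_b)
}
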