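#' Construct a compartment occupancy trace
#'
#' The record of a real-time place-preference session from the stimulation
#' controller's point of view: alternating entries into and exits from the
#' laser-paired compartment, as `(time, state)` events with state
#' `"in_paired"` or `"out"`. The state at `t = 0` is the first event, at
#' time 0.
#'
#' @param times Strictly increasing event times in seconds starting at 0.
#' @param states Character vector of `"in_paired"` / `"out"`, alternating.
#' @param session_length Session length in seconds; all events must precede
#'   it.
#' @return An object of class `occupancy_trace`: data frame `(time, state)`
#'   with a `session_length` attribute.
#' @export
occupancy_trace <- function(times, states, session_length) {
  times <- as.numeric(times); states <- as.character(states)
  if (length(times) != length(states))
    stop("times and states differ in length", call. = FALSE)
  if (!length(times) || times[1L] != 0)
    stop("the trace must define the state at t = 0", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  if (times[length(times)] >= session_length)
    stop("events must precede `session_length`", call. = FALSE)
  if (!all(states %in% c("in_paired", "out")))
    stop("states must be 'in_paired' or 'out'", call. = FALSE)
  if (length(states) > 1L && any(states[-1L] == states[-length(states)]))
    stop("states must alternate", call. = FALSE)
  structure(data.frame(time = times, state = states),
            session_length = session_length,
            class = c("occupancy_trace", "data.frame"))
}

#' Read / write an occupancy trace CSV
#'
#' CSV with header `time_s,state`, state spelled `in_paired` / `out`.
#'
#' @param trace An [occupancy_trace].
#' @param path CSV path.
#' @param session_length Session length in seconds (reading only).
#' @return For writing, `path` invisibly; for reading, an
#'   [occupancy_trace].
#' @export
write_occupancy <- function(trace, path) {
  stopifnot(inherits(trace, "occupancy_trace"))
  writeLines(c("time_s,state",
               sprintf("%.6f,%s", trace$time, trace$state)), path)
  invisible(path)
}

#' @rdname write_occupancy
#' @export
read_occupancy <- function(path, session_length) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "state") %in% names(df)))
    stop("expected header 'time_s,state' in ", path, call. = FALSE)
  occupancy_trace(df$time_s, df$state, session_length)
}

# in_paired intervals [enter, exit) of a trace, closed by session end
.paired_intervals <- function(trace) {
  sl <- attr(trace, "session_length")
  ends <- c(trace$time[-1L], sl)
  keep <- trace$state == "in_paired"
  cbind(enter = trace$time[keep], exit = ends[keep])
}

#' Simulate gated playback of a stimulation file
#'
#' Models the real-time place-preference delivery rule: the stimulation file
#' is "played" upon entry into the paired compartment and "paused" upon
#' exit, so no pattern element is skipped while the animal is outside. A
#' file clock advances only during `in_paired` state; a pulse with file
#' onset `f` is emitted at the session time at which the file clock reaches
#' `f`. Playback stops permanently once the file clock reaches the file
#' length — there is no rewind and no looping, so a file shorter than the
#' total paired dwell simply runs out. A pulse cut short by an exit (or by
#' file end) is truncated, not replayed; truncations are counted in the log.
#'
#' @param schedule The stimulation [pulse_schedule] (the "file"); its
#'   `total_duration` is the file length.
#' @param occupancy An [occupancy_trace].
#' @return An object of class `playback_log`: list with `emitted` (data
#'   frame `session_time_s`, `file_time_s` of pulse onsets, in order),
#'   `file_position_end` (file clock at session end, seconds), and
#'   `n_truncated`.
#' @export
gated_playback <- function(schedule, occupancy) {
  stopifnot(inherits(schedule, "pulse_schedule"),
            inherits(occupancy, "occupancy_trace"))
  iv <- .paired_intervals(occupancy)
  flen <- schedule$total_duration
  f <- 0
  sess <- numeric(0); ftimes <- numeric(0); trunc <- 0L
  for (r in seq_len(nrow(iv))) {
    if (f >= flen) break
    len <- iv[r, "exit"] - iv[r, "enter"]
    fend <- min(f + len, flen)
    hit <- schedule$onset >= f & schedule$onset < fend
    if (any(hit)) {
      ftimes <- c(ftimes, schedule$onset[hit])
      sess <- c(sess, iv[r, "enter"] + (schedule$onset[hit] - f))
      trunc <- trunc + sum(schedule$offset[hit] > fend)
    }
    f <- fend
  }
  structure(list(emitted = data.frame(session_time_s = sess,
                                      file_time_s = ftimes),
                 file_position_end = f, n_truncated = trunc),
            class = "playback_log")
}

#' @export
print.playback_log <- function(x, ...) {
  cat(sprintf("<playback_log> %d pulse(s) emitted, file position %.2f s, %d truncated\n",
              nrow(x$emitted), x$file_position_end, x$n_truncated))
  invisible(x)
}

#' Preference score of a session
#'
#' Total dwell time in the laser-paired compartment, the raw score of a
#' place-preference session.
#'
#' @param occupancy An [occupancy_trace].
#' @return Seconds spent in the paired compartment.
#' @export
preference_score <- function(occupancy) {
  stopifnot(inherits(occupancy, "occupancy_trace"))
  iv <- .paired_intervals(occupancy)
  sum(iv[, "exit"] - iv[, "enter"])
}

#' Percent change from pre-test
#'
#' Group scores are conventionally normalized to the percentage change from
#' the stimulation-free pre-test: `100 * (test - pretest) / pretest`.
#'
#' @param test_score Test-day preference score in seconds.
#' @param pretest_score Pre-test preference score in seconds; must be
#'   positive.
#' @return Percent change (positive = preference shift toward the paired
#'   side).
#' @export
percent_change <- function(test_score, pretest_score) {
  if (!is.numeric(pretest_score) || any(pretest_score <= 0))
    stop("`pretest_score` must be positive", call. = FALSE)
  100 * (test_score - pretest_score) / pretest_score
}

#' Assign the stimulation compartment from pre-test scores
#'
#' Protocol bookkeeping for conditioning-day design: stimulation predicted
#' to be rewarding is paired to the least-preferred compartment at
#' pre-test, predicted-aversive stimulation to the preferred one, and with
#' no prediction an unbiased (seeded random) assignment is made. This is a
#' pure helper encoding the counterbalancing recipe, not a behavioral
#' model.
#'
#' @param pretest_scores Named numeric vector of per-compartment pre-test
#'   dwell times (seconds), e.g. `c(left = 500, right = 400)`.
#' @param hypothesis `"rewarding"`, `"aversive"`, or `"none"`.
#' @param seed Seed for the unbiased case.
#' @return The name of the compartment to pair with stimulation.
#' @export
assign_compartment <- function(pretest_scores,
                               hypothesis = c("rewarding", "aversive", "none"),
                               seed = NULL) {
  hypothesis <- match.arg(hypothesis)
  if (length(pretest_scores) < 2L || is.null(names(pretest_scores)))
    stop("`pretest_scores` must be a named vector of >= 2 compartments",
         call. = FALSE)
  switch(hypothesis,
         rewarding = names(pretest_scores)[which.min(pretest_scores)],
         aversive = names(pretest_scores)[which.max(pretest_scores)],
         none = with_seed(seed, sample(names(pretest_scores), 1L)))
}
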