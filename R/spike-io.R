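#' @importFrom stats rexp rgamma rnorm rpois runif
#' @importFrom utils read.csv write.csv head tail
NULL

.conditions <- c("baseline", "saline", "morphine", "shuffled")

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user simulations.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Construct a spike train
#'
#' A spike train is the ordered set of action-potential timestamps of one
#' sorted unit within a fixed-length recording segment (for example a 15-min
#' baseline, saline, or morphine condition), plus identifying metadata.
#'
#' @param timestamps Numeric vector of spike times in seconds, strictly
#'   increasing, all within `[0, duration]`. May be empty.
#' @param duration Length of the recording segment in seconds; must be
#'   positive and at least the last timestamp.
#' @param unit_id Identifier of the sorted unit.
#' @param condition One of `"baseline"`, `"saline"`, `"morphine"`, or
#'   `"shuffled"` (the tag applied to ISI-shuffled surrogates).
#' @param dose_mg_per_kg Optional drug dose annotation (mg/kg).
#' @param subject_id Optional subject identifier.
#' @param sort If `TRUE`, unsorted timestamps are sorted with a warning
#'   instead of raising an error (spike-sorter exports vary in ordering).
#' @return An object of class `spike_train`: a list with elements
#'   `timestamps`, `duration`, `unit_id`, `condition`, `dose_mg_per_kg`,
#'   `subject_id`.
#' @export
spike_train <- function(timestamps, duration, unit_id = "unit",
                        condition = "baseline", dose_mg_per_kg = NULL,
                        subject_id = NULL, sort = FALSE) {
  timestamps <- as.numeric(timestamps)
  if (anyNA(timestamps)) stop("timestamps contain NA", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) ||
      duration <= 0)
    stop("`duration` must be a single positive number (seconds)", call. = FALSE)
  condition <- match.arg(condition, .conditions)
  if (is.unsorted(timestamps, strictly = FALSE)) {
    if (!sort)
      stop("timestamps are not sorted; pass sort = TRUE to sort with a warning",
           call. = FALSE)
    warning("unsorted timestamps were sorted on input", call. = FALSE)
    timestamps <- base::sort(timestamps)
  }
  if (length(timestamps)) {
    if (timestamps[1L] < 0)
      stop("negative timestamp: spike times must be >= 0", call. = FALSE)
    if (timestamps[length(timestamps)] > duration)
      stop("timestamp exceeds segment duration (", duration, " s)",
           call. = FALSE)
    if (any(diff(timestamps) <= 0))
      stop("duplicate timestamps: spike times must be strictly increasing",
           call. = FALSE)
  }
  structure(
    list(timestamps = timestamps, duration = duration, unit_id = unit_id,
         condition = condition, dose_mg_per_kg = dose_mg_per_kg,
         subject_id = subject_id),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit '%s', condition %s: %d spikes over %.1f s (%.2f spikes/s)\n",
              x$unit_id, x$condition, length(x$timestamps), x$duration,
              length(x$timestamps) / x$duration))
  invisible(x)
}

#' Read a spike train from a timestamp file
#'
#' Reads one timestamp per line (or a single-column CSV, optionally with a
#' header) in seconds, together with an optional JSON metadata sidecar
#' carrying `unit_id`, `condition`, `dose_mg_per_kg`, `subject_id` and
#' `duration_s`. Unsorted files are sorted with a warning.
#'
#' @param path Timestamp file path.
#' @param metadata Optional path to the JSON sidecar. Fields in the sidecar
#'   override the corresponding arguments.
#' @param duration Segment duration in seconds; required unless the sidecar
#'   provides `duration_s`.
#' @inheritParams spike_train
#' @return A [spike_train].
#' @export
read_spike_train <- function(path, metadata = NULL, duration = NULL,
                             unit_id = "unit", condition = "baseline",
                             dose_mg_per_kg = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) && is.na(suppressWarnings(as.numeric(lines[1L]))))
    lines <- lines[-1L]                      # header row
  ts <- suppressWarnings(as.numeric(lines))
  if (anyNA(ts)) stop("non-numeric timestamp in ", path, call. = FALSE)
  if (!is.null(metadata)) {
    meta <- jsonlite::read_json(metadata, simplifyVector = TRUE)
    if (!is.null(meta$unit_id)) unit_id <- meta$unit_id
    if (!is.null(meta$condition)) condition <- meta$condition
    if (!is.null(meta$dose_mg_per_kg)) dose_mg_per_kg <- meta$dose_mg_per_kg
    if (!is.null(meta$subject_id)) subject_id <- meta$subject_id
    if (!is.null(meta$duration_s)) duration <- meta$duration_s
  }
  if (is.null(duration))
    stop("`duration` must be given directly or as `duration_s` in the sidecar",
         call. = FALSE)
  spike_train(ts, duration = duration, unit_id = unit_id,
              condition = condition, dose_mg_per_kg = dose_mg_per_kg,
              subject_id = subject_id, sort = TRUE)
}

#' Write a spike train and its metadata sidecar
#'
#' Timestamps are written one per line with six decimal places (1 microsecond,
#' finer than the 30 kHz acquisition grid), so write/read round trips are
#' faithful at the stored precision.
#'
#' @param train A [spike_train].
#' @param path Output timestamp file path.
#' @param metadata Optional path for the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_spike_train <- function(train, path, metadata = NULL) {
  stopifnot(inherits(train, "spike_train"))
  writeLines(sprintf("%.6f", train$timestamps), path)
  if (!is.null(metadata)) {
    meta <- list(unit_id = train$unit_id, condition = train$condition,
                 duration_s = train$duration)
    if (!is.null(train$dose_mg_per_kg)) meta$dose_mg_per_kg <- train$dose_mg_per_kg
    if (!is.null(train$subject_id)) meta$subject_id <- train$subject_id
    jsonlite::write_json(meta, metadata, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Construct a mean unit waveform
#'
#' @param samples Numeric vector of voltage samples (arbitrary units), at
#'   least 8 samples long.
#' @param sample_rate Sampling rate in Hz (default 30000, the acquisition
#'   rate of the extracellular recordings this models).
#' @param unit_id Identifier of the unit.
#' @return An object of class `unit_waveform`.
#' @export
unit_waveform <- function(samples, sample_rate = 30000, unit_id = "unit") {
  samples <- as.numeric(samples)
  if (length(samples) < 8L) stop("waveform needs >= 8 samples", call. = FALSE)
  if (anyNA(samples)) stop("waveform samples contain NA", call. = FALSE)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("`sample_rate` must be positive", call. = FALSE)
  structure(list(samples = samples, sample_rate = sample_rate,
                 unit_id = unit_id),
            class = "unit_waveform")
}

#' Construct a pulse schedule
#'
#' A pulse schedule is the universal representation of a stimulation file:
#' an ordered set of non-overlapping light-on intervals on `[0,
#' total_duration]`, with free-form annotation (wavelength, power, pattern
#' mode, provenance).
#'
#' @param onsets Numeric vector of light-on times (seconds).
#' @param offsets Numeric vector of light-off times, same length; each
#'   `offsets[i] > onsets[i]` and intervals must not overlap.
#' @param total_duration Schedule length in seconds.
#' @param pulse_width Nominal pulse width in seconds (default 0.003, the 3 ms
#'   pulse used for fast-opsin stimulation).
#' @param annotation Named list of metadata (e.g. `wavelength_nm`,
#'   `power_mW`, `pattern_mode`, provenance).
#' @return An object of class `pulse_schedule` with elements `onset`,
#'   `offset`, `total_duration`, `pulse_width`, `annotation`.
#' @export
pulse_schedule <- function(onsets, offsets, total_duration,
                           pulse_width = 0.003, annotation = list()) {
  onsets <- as.numeric(onsets); offsets <- as.numeric(offsets)
  if (length(onsets) != length(offsets))
    stop("onsets and offsets differ in length", call. = FALSE)
  if (!is.numeric(total_duration) || total_duration < 0)
    stop("`total_duration` must be non-negative", call. = FALSE)
  if (!is.numeric(pulse_width) || pulse_width <= 0)
    stop("`pulse_width` must be positive", call. = FALSE)
  if (length(onsets)) {
    if (any(offsets <= onsets))
      stop("each off_time must exceed its on_time", call. = FALSE)
    if (onsets[1L] < 0 || offsets[length(offsets)] > total_duration + 1e-9)
      stop("intervals must lie within [0, total_duration]", call. = FALSE)
    if (length(onsets) > 1L && any(onsets[-1L] < offsets[-length(offsets)]))
      stop("intervals overlap or are out of order", call. = FALSE)
  }
  structure(list(onset = onsets, offset = offsets,
                 total_duration = total_duration, pulse_width = pulse_width,
                 annotation = annotation),
            class = "pulse_schedule")
}

#' @export
print.pulse_schedule <- function(x, ...) {
  mode <- x$annotation$pattern_mode
  cat(sprintf("<pulse_schedule>%s %d on-interval(s) over %.1f s, light-on %.3f s total\n",
              if (is.null(mode)) "" else paste0(" [", mode, "]"),
              length(x$onset), x$total_duration, sum(x$offset - x$onset)))
  invisible(x)
}

n_pulses <- function(schedule) length(schedule$onset)

#' Write / read pulse-event CSV
#'
#' The on/off intervals of a schedule are stored as a CSV with header
#' `onset_s,offset_s` and six-decimal times; the write/read round trip is
#' faithful at that precision.
#'
#' @param schedule A [pulse_schedule].
#' @param path CSV path.
#' @return For writing, `path` invisibly; for reading, a [pulse_schedule].
#' @export
write_pulse_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  lines <- c("onset_s,offset_s",
             sprintf("%.6f,%.6f", schedule$onset, schedule$offset))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pulse_events
#' @param total_duration Schedule length in seconds; defaults to the last
#'   offset in the file (0 for an empty file).
#' @param pulse_width,annotation Passed to [pulse_schedule()].
#' @export
read_pulse_events <- function(path, total_duration = NULL,
                              pulse_width = 0.003, annotation = list()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("onset_s", "offset_s") %in% names(df)))
    stop("expected header 'onset_s,offset_s' in ", path, call. = FALSE)
  if (is.null(total_duration))
    total_duration <- if (nrow(df)) max(df$offset_s) else 0
  pulse_schedule(df$onset_s, df$offset_s, total_duration,
                 pulse_width = pulse_width, annotation = annotation)
}

#' Render a pulse schedule as a normalized square wave
#'
#' Sample `i` (0-based) is 1 exactly when its time `i / sample_rate` falls in
#' the half-open interval `[on, off)` of some scheduled pulse, else 0 — the
#' "0 to 1" normalized square signal that drives a laser trigger line.
#'
#' @param schedule A [pulse_schedule].
#' @param sample_rate Samples per second; must be at least
#'   `2 / pulse_width` so every pulse spans two or more samples.
#' @return An object of class `wave_render`: list with binary `samples` and
#'   `sample_rate`.
#' @export
render_wave <- function(schedule, sample_rate = 44100) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  min_rate <- 2 / schedule$pulse_width
  if (sample_rate < min_rate)
    stop(sprintf("sample_rate %g Hz too low for %.4g s pulses; need >= %g Hz",
                 sample_rate, schedule$pulse_width, min_rate), call. = FALSE)
  n <- round(schedule$total_duration * sample_rate)
  samples <- numeric(n)
  eps <- 1e-9
  for (k in seq_along(schedule$onset)) {
    i0 <- ceiling(schedule$onset[k] * sample_rate - eps)
    i1 <- ceiling(schedule$offset[k] * sample_rate - eps) - 1
    i0 <- max(i0, 0); i1 <- min(i1, n - 1)
    if (i1 >= i0) samples[(i0 + 1):(i1 + 1)] <- 1
  }
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "wave_render")
}

#' Decode a square wave back into a pulse schedule
#'
#' Maximal runs of 1-samples become on-intervals; used to verify rendered
#' files and to ingest externally produced trigger waves.
#'
#' @param render A `wave_render` (or any list with binary `samples` and
#'   `sample_rate`).
#' @return A [pulse_schedule] whose edges lie on the sample grid.
#' @export
decode_wave <- function(render) {
  s <- render$samples
  if (!all(s %in% c(0, 1)))
    stop("samples must be binary (0/1); got other values", call. = FALSE)
  r <- render$sample_rate
  total <- length(s) / r
  if (!length(s) || !any(s == 1))
    return(pulse_schedule(numeric(0), numeric(0), total))
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths      # 0-based start index of each run
  on <- runs$values == 1
  pulse_schedule(starts[on] / r, ends[on] / r, total,
                 pulse_width = min((ends[on] - starts[on]) / r))
}

#' Write / read a mono PCM wave file
#'
#' Writes the rendered square signal as a canonical 16-bit mono PCM RIFF/WAVE
#' file, with logical 1 mapped to full-scale positive (the normalized "0 to
#' 1" amplitude convention; hardware volume scaling is outside the package's
#' scope). Reading thresholds samples at half scale back to binary.
#'
#' @param render A `wave_render`.
#' @param path Wave file path.
#' @return For writing, `path` invisibly; for reading, a `wave_render` with
#'   binary samples.
#' @export
write_wave_file <- function(render, path) {
  data <- as.integer(round(render$samples) * 32767L)
  sr <- as.integer(round(render$sample_rate))
  nbytes <- 2L * length(data)
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + nbytes, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")       # fmt chunk size
  writeBin(1L, con, size = 2L, endian = "little")        # PCM
  writeBin(1L, con, size = 2L, endian = "little")        # mono
  writeBin(sr, con, size = 4L, endian = "little")
  writeBin(sr * 2L, con, size = 4L, endian = "little")   # byte rate
  writeBin(2L, con, size = 2L, endian = "little")        # block align
  writeBin(16L, con, size = 2L, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4L, endian = "little")
  writeBin(data, con, size = 2L, endian = "little")
  invisible(path)
}

#' @rdname write_wave_file
#' @export
read_wave_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readChar(con, 4L)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  if (!identical(readChar(con, 4L), "WAVE"))
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  sr <- NULL; data <- NULL
  repeat {
    tag <- readChar(con, 4L)
    if (!length(tag) || !nzchar(tag)) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(tag, "fmt ")) {
      fmt <- readBin(con, "integer", 2L, size = 2L, endian = "little")
      sr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      invisible(readBin(con, "raw", size - 8L))
      if (fmt[1L] != 1L || fmt[2L] != 1L)
        stop("only mono PCM wave files are supported", call. = FALSE)
    } else if (identical(tag, "data")) {
      data <- readBin(con, "integer", size %/% 2L, size = 2L,
                      endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(sr) || is.null(data)) stop("malformed wave file", call. = FALSE)
  structure(list(samples = as.numeric(data > 16383L), sample_rate = sr),
            class = "wave_render")
}

#' Write / read a TTL event list
#'
#' A schedule's edges as a CSV `time_s,state` with state 1 at each light-on
#' edge and 0 at each light-off edge, the form consumed by TTL trigger
#' loggers.
#'
#' @inheritParams write_pulse_events
#' @export
write_ttl_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  n <- length(schedule$onset)
  lines <- "time_s,state"
  if (n) {
    t <- as.vector(rbind(schedule$onset, schedule$offset))
    s <- rep(c(1L, 0L), n)
    lines <- c(lines, sprintf("%.6f,%d", t, s))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ttl_events
#' @param total_duration Schedule length; defaults to the last off edge.
#' @export
read_ttl_events <- function(path, total_duration = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "state") %in% names(df)))
    stop("expected header 'time_s,state' in ", path, call. = FALSE)
  if (nrow(df) %% 2L || (nrow(df) && !all(df$state == rep(c(1L, 0L), nrow(df) / 2L))))
    stop("TTL events must alternate 1/0 starting with 1", call. = FALSE)
  on <- df$time_s[df$state == 1L]; off <- df$time_s[df$state == 0L]
  if (is.null(total_duration)) total_duration <- if (length(off)) max(off) else 0
  pulse_schedule(on, off, total_duration)
}
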