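#' Run the stimulation-design pipeline from a configuration
#'
#' Wires the stages of the toolkit — simulate or load a spike train,
#' classify the unit, scan for bursts, generate a stimulation pattern,
#' render it, simulate gated session playback, and score preference — from
#' a single serializable configuration, writing every artifact with a
#' provenance sidecar and returning a checksum manifest. A stored
#' configuration (with its seeds) regenerates byte-identical outputs.
#'
#' The configuration is a named list (or path to a JSON file) with an
#' `out_dir`, an optional `prefix` and `seed`, and any of the stage blocks:
#' \describe{
#'   \item{`simulate_train`}{arguments for [simulate_train()]; the result
#'     becomes the working train.}
#'   \item{`train` / `train_meta`}{paths read with [read_spike_train()]
#'     (alternative to simulation). `duration_s` may be given in the
#'     sidecar or as `duration`.}
#'   \item{`simulate_waveform`}{arguments for [simulate_waveform()], or
#'     `waveform`: a single-column CSV of samples (with `waveform_rate`).}
#'   \item{`classify`}{`true` to classify the unit (requires a train and a
#'     waveform); writes a JSON report.}
#'   \item{`burstscan`}{`true` or a list of [burst_params()] overrides;
#'     writes a burst CSV and summary JSON.}
#'   \item{`generate`}{list with `mode` in `biomimetic`, `shuffled`,
#'     `tonic`, `continuous` plus mode arguments (`seed`, `rate`,
#'     `duration`, `on_s`, `off_s`, `pulse_width`); writes the pulse-event
#'     CSV and provenance JSON.}
#'   \item{`render`}{`true` or list with `sample_rate`; writes a wave
#'     file and TTL event CSV for the generated schedule.}
#'   \item{`playback`}{list with `occupancy` (CSV path) and
#'     `session_length`, or `simulate` (arguments for
#'     [simulate_occupancy()]); writes the playback log CSV.}
#'   \item{`score`}{`true`; writes preference score (and percent change if
#'     `pretest_score_s` is supplied) as JSON.}
#' }
#'
#' @param config Named list or path to a JSON configuration file.
#' @return Invisibly, the manifest: a data frame with `file` and `md5` for
#'   every artifact written, also saved as `<prefix>_manifest.json`. A
#'   stage failure aborts with an error naming the stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$out_dir)) stop("config needs `out_dir`", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- if (is.null(config$prefix)) "run" else config$prefix
  path_for <- function(name) file.path(config$out_dir, paste0(prefix, "_", name))
  artifacts <- character(0)
  emit <- function(p) artifacts <<- c(artifacts, p)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  train <- NULL; wf <- NULL; sched <- NULL
  if (!is.null(config$simulate_train)) {
    train <- stage("simulate_train", {
      args <- config$simulate_train
      if (is.null(args$seed)) args$seed <- config$seed
      tr <- do.call(simulate_train, args)
      p <- path_for("train.csv"); m <- path_for("train.json")
      write_spike_train(tr, p, metadata = m)
      emit(p); emit(m)
      tr
    })
  } else if (!is.null(config$train)) {
    train <- stage("read_train",
      read_spike_train(config$train, metadata = config$train_meta,
                       duration = config$duration))
  }
  if (!is.null(config$simulate_waveform)) {
    wf <- stage("simulate_waveform", {
      args <- config$simulate_waveform
      if (is.null(args$seed)) args$seed <- config$seed
      do.call(simulate_waveform, args)
    })
  } else if (!is.null(config$waveform)) {
    wf <- stage("read_waveform", {
      df <- utils::read.csv(config$waveform)
      rate <- if (is.null(config$waveform_rate)) 30000 else config$waveform_rate
      unit_waveform(df[[1L]], sample_rate = rate)
    })
  }

  if (isTRUE(config$classify)) {
    stage("classify", {
      if (is.null(train) || is.null(wf))
        stop("classification requires a train and a waveform")
      lab <- classify(train, wf)
      p <- path_for("classification.json")
      jsonlite::write_json(unclass(lab), p, auto_unbox = TRUE, digits = NA)
      emit(p)
    })
  }

  if (!is.null(config$burstscan) && !isFALSE(config$burstscan)) {
    stage("burstscan", {
      if (is.null(train)) stop("burst scan requires a train")
      pars <- if (is.list(config$burstscan))
        do.call(burst_params, config$burstscan) else burst_params()
      b <- detect_bursts(train, pars)
      p <- path_for("bursts.csv")
      utils::write.csv(as.data.frame(b)[, c("start", "end", "n_spikes", "duration")],
                       p, row.names = FALSE)
      s <- path_for("burst_summary.json")
      jsonlite::write_json(burst_summary(b, train), s, auto_unbox = TRUE,
                           digits = NA)
      emit(p); emit(s)
    })
  }

  if (!is.null(config$generate)) {
    sched <- stage("generate", {
      g <- config$generate
      pw <- if (is.null(g$pulse_width)) 0.003 else g$pulse_width
      mode <- match.arg(g$mode, c("biomimetic", "shuffled", "tonic", "continuous"))
      sc <- switch(mode,
        biomimetic = {
          if (is.null(train)) stop("biomimetic mode requires a train")
          biomimetic_pattern(train, pulse_width = pw)
        },
        shuffled = {
          if (is.null(train)) stop("shuffled mode requires a train")
          sd <- if (is.null(g$seed)) config$seed else g$seed
          if (is.null(sd)) stop("shuffled mode requires a seed")
          biomimetic_pattern(shuffle_isis(train, sd), pulse_width = pw)
        },
        tonic = {
          rate <- if (is.null(g$rate)) mean_rate(train) else g$rate
          dur <- if (!is.null(g$duration)) g$duration else train$duration
          tonic_pattern(rate, dur, pulse_width = pw)
        },
        continuous = {
          dur <- if (!is.null(g$duration)) g$duration else train$duration
          continuous_pattern(dur,
                             on_duration = if (is.null(g$on_s)) 30 else g$on_s,
                             off_duration = if (is.null(g$off_s)) 60 else g$off_s)
        })
      p <- path_for("pulses.csv")
      write_pulse_events(sc, p); emit(p)
      prov <- path_for("pulses_provenance.json")
      jsonlite::write_json(c(list(mode = mode), sc$annotation,
                             list(seed = if (mode == "shuffled")
                               (if (is.null(g$seed)) config$seed else g$seed)
                               else NULL,
                               total_duration_s = sc$total_duration,
                               pulse_width_s = sc$pulse_width)),
                           prov, auto_unbox = TRUE, digits = NA)
      emit(prov)
      sc
    })
  }

  if (!is.null(config$render) && !isFALSE(config$render)) {
    stage("render", {
      if (is.null(sched)) stop("render requires a generated schedule")
      sr <- if (is.list(config$render) && !is.null(config$render$sample_rate))
        config$render$sample_rate else 44100
      wv <- render_wave(sched, sample_rate = sr)
      p <- path_for("stim.wav"); write_wave_file(wv, p); emit(p)
      t <- path_for("ttl.csv"); write_ttl_events(sched, t); emit(t)
    })
  }

  log <- NULL; occ <- NULL
  if (!is.null(config$playback)) {
    log <- stage("playback", {
      if (is.null(sched)) stop("playback requires a generated schedule")
      pb <- config$playback
      occ <- if (!is.null(pb$simulate)) {
        args <- pb$simulate
        if (is.null(args$seed)) args$seed <- config$seed
        do.call(simulate_occupancy, args)
      } else {
        if (is.null(pb$occupancy) || is.null(pb$session_length))
          stop("playback requires `occupancy` + `session_length` or `simulate`")
        read_occupancy(pb$occupancy, pb$session_length)
      }
      lg <- gated_playback(sched, occ)
      p <- path_for("playback.csv")
      utils::write.csv(lg$emitted, p, row.names = FALSE); emit(p)
      lg
    })
  }
  if (isTRUE(config$score)) {
    stage("score", {
      if (is.null(occ)) stop("scoring requires an occupancy trace")
      res <- list(time_in_paired_s = preference_score(occ),
                  session_length_s = attr(occ, "session_length"))
      if (!is.null(config$pretest_score_s))
        res$percent_change_from_pretest <-
          percent_change(res$time_in_paired_s, config$pretest_score_s)
      p <- path_for("score.json")
      jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA); emit(p)
    })
  }

  manifest <- data.frame(file = artifacts,
                         md5 = unname(tools::md5sum(artifacts)),
                         row.names = NULL)
  mp <- path_for("manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
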