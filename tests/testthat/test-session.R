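test_that("gated playback pauses and resumes the file clock on exit/entry", {
  file_900 <- tonic_pattern(2, 900)
  stay <- occupancy_trace(0, "in_paired", 900)
  lg <- gated_playback(file_900, stay)
  expect_equal(lg$emitted$session_time_s, lg$emitted$file_time_s)
  expect_equal(nrow(lg$emitted), length(file_900$onset))
  expect_equal(lg$file_position_end, 900)

  never <- occupancy_trace(0, "out", 900)
  lg0 <- gated_playback(file_900, never)
  expect_equal(nrow(lg0$emitted), 0)
  expect_equal(lg0$file_position_end, 0)

  # in 0-10 s, out 10-20 s, in 20-900 s; file pulses at 2 s and 12 s
  occ <- occupancy_trace(c(0, 10, 20), c("in_paired", "out", "in_paired"), 900)
  two <- pulse_schedule(c(2, 12), c(2.003, 12.003), 900)
  lg2 <- gated_playback(two, occ)
  expect_equal(lg2$emitted$file_time_s, c(2, 12))
  expect_equal(lg2$emitted$session_time_s, c(2, 22))
})

test_that("playback stops at file end and truncates interrupted pulses", {
  short_file <- tonic_pattern(1, 10)        # 10 s file, session longer
  occ <- occupancy_trace(0, "in_paired", 60)
  lg <- gated_playback(short_file, occ)
  expect_equal(nrow(lg$emitted), 10)
  expect_equal(lg$file_position_end, 10)    # no looping past the file

  # exit slices through the middle of a pulse
  cut <- occupancy_trace(c(0, 1.0015, 3), c("in_paired", "out", "in_paired"), 10)
  one <- pulse_schedule(1, 1.003, 10)
  lgc <- gated_playback(one, cut)
  expect_equal(lgc$n_truncated, 1L)
  expect_equal(nrow(lgc$emitted), 1)        # truncated, not replayed
})

test_that("emission count and relative timing obey the conservation rules", {
  set.seed(41)
  file_len <- 60
  sched <- tonic_pattern(5, file_len)
  for (i in 1:40) {
    occ <- simulate_occupancy(bias = runif(1, 0.2, 0.8), mean_dwell = 15,
                              session_length = 150, seed = i)
    dwell <- preference_score(occ)
    lg <- gated_playback(sched, occ)
    expect_lte(nrow(lg$emitted), length(sched$onset))
    # discreteness guard: near-equality of dwell and file length leaves no
    # pulse between the final file position and the file end
    if (abs(dwell - file_len) > 1 / 5) {
      expect_equal(nrow(lg$emitted) == length(sched$onset), dwell >= file_len)
    }
    if (nrow(lg$emitted) > 1) {
      expect_equal(diff(lg$emitted$file_time_s),
                   diff(sched$onset[seq_len(nrow(lg$emitted))]))
      expect_true(all(diff(lg$emitted$file_time_s) > 0))
    }
  }
})

test_that("preference scores sum dwell time and normalize to pre-test", {
  expect_equal(preference_score(occupancy_trace(0, "in_paired", 900)), 900)
  alt <- occupancy_trace(seq(0, 90, by = 10),
                         rep(c("in_paired", "out"), 5), 100)
  expect_equal(preference_score(alt), 50)
  expect_equal(preference_score(occupancy_trace(0, "out", 900)), 0)

  # dwell accounting: in-time plus out-time is the session length
  set.seed(42)
  for (i in 1:30) {
    occ <- simulate_occupancy(bias = runif(1, 0.1, 0.9), mean_dwell = 20,
                              session_length = 300, seed = 1000 + i)
    iv <- occ
    out_time <- 300 - preference_score(occ)
    expect_gte(out_time, 0)
    expect_equal(preference_score(occ) + out_time, 300)
  }

  expect_equal(percent_change(450, 300), 50)
  expect_equal(percent_change(300, 300), 0)
  expect_equal(percent_change(300, 400), -25)
  expect_error(percent_change(100, 0), "positive")
})

test_that("occupancy traces validate and round trip through CSV", {
  expect_error(occupancy_trace(c(0, 5), c("in_paired", "in_paired"), 10),
               "alternate")
  expect_error(occupancy_trace(c(1, 5), c("in_paired", "out"), 10), "t = 0")
  expect_error(occupancy_trace(c(0, 11), c("in_paired", "out"), 10),
               "session_length")

  occ <- occupancy_trace(c(0, 12.5, 30), c("out", "in_paired", "out"), 60)
  f <- withr::local_tempfile(fileext = ".csv")
  write_occupancy(occ, f)
  back <- read_occupancy(f, 60)
  expect_equal(back$time, occ$time)
  expect_equal(back$state, occ$state)
  expect_equal(preference_score(back), 17.5)
})

test_that("compartment assignment follows the counterbalancing recipe", {
  scores <- c(left = 520, right = 380)
  expect_equal(assign_compartment(scores, "rewarding"), "right")
  expect_equal(assign_compartment(scores, "aversive"), "left")
  expect_identical(assign_compartment(scores, "none", seed = 5),
                   assign_compartment(scores, "none", seed = 5))
})
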