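test_that("train simulation is seeded, refractory-respecting, and validated", {
  a <- simulate_train(18.8, 60, seed = 1)
  b <- simulate_train(18.8, 60, seed = 1)
  expect_identical(a$timestamps, b$timestamps)
  expect_false(identical(a$timestamps, simulate_train(18.8, 60, seed = 2)$timestamps))

  for (seed in 1:5) {
    tr <- simulate_train(30, 30, isi_cv = 1.5, refractory = 0.002, seed = seed,
                         bursts = list(events_per_s = 0.3))
    expect_gte(min(diff(tr$timestamps)), 0.002)
    expect_lte(max(tr$timestamps), 30)
  }
  expect_error(simulate_train(600, 10, refractory = 0.002), "infeasible")
})

test_that("simulated trains recover their configured mean rate", {
  for (rate in c(16.7, 22.2)) {
    realized <- vapply(1:8, function(s)
      mean_rate(simulate_train(rate, 300, seed = s)), 0)
    expect_lt(abs(mean(realized) - rate) / rate, 0.05)
  }
})

test_that("waveform generator closes the loop with the analyzer exactly", {
  for (ptt in c(0.0001, 0.0002, 0.0003, 0.0004, 0.0006)) {
    wf <- simulate_waveform(ptt, sample_rate = 30000)
    expect_equal(peak_to_trough(wf), round(ptt * 30000) / 30000)
  }
  expect_equal(peak_to_trough(simulate_waveform(0.0002)), 0.0002)
  expect_error(simulate_waveform(1e-6, sample_rate = 30000), "below one sample")

  # a wide (0.6 ms) waveform fails the putative-GABA criteria even at 20 Hz
  wide <- simulate_waveform(0.0006)
  expect_equal(classify_unit(peak_to_trough(wide), 20)$label, "other")

  expect_identical(simulate_waveform(0.0003, noise_sd = 0.05, seed = 3)$samples,
                   simulate_waveform(0.0003, noise_sd = 0.05, seed = 3)$samples)
})

test_that("classification of narrow waveforms tolerates moderate noise", {
  labels <- vapply(1:100, function(s) {
    wf <- simulate_waveform(0.0002, noise_sd = 0.05, seed = s)
    classify_unit(peak_to_trough(wf), 20)$label
  }, "")
  expect_gte(mean(labels == "putative_GABA"), 0.95)
})

test_that("occupancy simulation hits its long-run bias and is reproducible", {
  frac <- vapply(1:200, function(s)
    preference_score(simulate_occupancy(0.5, mean_dwell = 20,
                                        session_length = 600, seed = s)) / 600, 0)
  expect_gte(mean(frac), 0.45)
  expect_lte(mean(frac), 0.55)

  high <- vapply(1:50, function(s)
    preference_score(simulate_occupancy(0.95, mean_dwell = 20,
                                        session_length = 600, seed = s)) / 600, 0)
  expect_gt(mean(high), 0.85)

  o1 <- simulate_occupancy(0.6, 15, 300, seed = 9)
  o2 <- simulate_occupancy(0.6, 15, 300, seed = 9)
  expect_identical(o1$time, o2$time)
  expect_error(simulate_occupancy(1, 10, 100), "bias")
})

test_that("injected bursts satisfying the criteria are recovered", {
  # overlay bursts at known times on an irregular background, then ask the
  # detector at defaults to find them
  recovered <- 0L; injected <- 0L
  for (seed in 1:20) {
    dur <- 120
    base <- simulate_train(16.7, dur, seed = seed)
    starts <- seq(5, dur - 5, by = 10)
    ts <- base$timestamps
    for (t0 in starts) {
      burst <- t0 + cumsum(c(0, rep(0.006, 6)))   # 7 spikes, 36 ms span
      ts <- c(ts, burst)
    }
    ts <- sort(ts)
    keep <- c(TRUE, diff(ts) >= 0.002)
    tr2 <- spike_train(ts[keep & ts <= dur], dur, condition = "morphine")
    det <- detect_bursts(tr2)
    injected <- injected + length(starts)
    recovered <- recovered + sum(vapply(starts, function(t0)
      any(det$start <= t0 + 0.036 & det$end >= t0), NA))
  }
  expect_gte(recovered / injected, 0.9)
})

test_that("the study presets encode the three source recordings", {
  cfg <- study_train_configs()
  expect_equal(cfg$morphine_1$mean_rate, 18.8)
  expect_equal(cfg$morphine_2$mean_rate, 22.2)
  expect_equal(cfg$baseline$mean_rate, 16.7)
  expect_equal(cfg$morphine_1$duration, 900)
  expect_false(is.null(cfg$morphine_2$bursts))
  expect_equal(cfg$baseline$condition, "baseline")
})
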