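test_that("spike train files parse, validate, and sort with a warning", {
  f <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("0.010", "0.050", "0.100"), f)
  tr <- read_spike_train(f, duration = 1.0)
  expect_equal(tr$timestamps, c(0.010, 0.050, 0.100))

  writeLines(character(0), f)
  empty <- read_spike_train(f, duration = 900)
  expect_length(empty$timestamps, 0)
  expect_equal(mean_rate(empty), 0)

  writeLines(c("0.5", "0.2"), f)
  expect_warning(tr2 <- read_spike_train(f, duration = 1.0), "sorted")
  expect_equal(tr2$timestamps, c(0.2, 0.5))

  writeLines("-0.1", f)
  expect_error(read_spike_train(f, duration = 1), "negative")
  writeLines("2.0", f)
  expect_error(read_spike_train(f, duration = 1), "duration")
})

test_that("spike train write/read round trips with the metadata sidecar", {
  f <- withr::local_tempfile(fileext = ".csv")
  m <- withr::local_tempfile(fileext = ".json")
  tr <- spike_train(c(0.000001, 0.25, 899.999999), 900, unit_id = "cell2",
                    condition = "morphine", dose_mg_per_kg = 15)
  write_spike_train(tr, f, metadata = m)
  back <- read_spike_train(f, metadata = m)
  expect_equal(back$timestamps, tr$timestamps)
  expect_equal(back$duration, 900)
  expect_equal(back$unit_id, "cell2")
  expect_equal(back$condition, "morphine")
  expect_equal(back$dose_mg_per_kg, 15)
})

test_that("pulse-event CSV has the documented shape and round trips", {
  f <- withr::local_tempfile(fileext = ".csv")
  one <- pulse_schedule(0, 0.003, total_duration = 1)
  write_pulse_events(one, f)
  expect_equal(readLines(f), c("onset_s,offset_s", "0.000000,0.003000"))

  write_pulse_events(pulse_schedule(numeric(0), numeric(0), 1), f)
  expect_equal(readLines(f), "onset_s,offset_s")

  set.seed(11)
  for (i in 1:20) {
    s <- random_schedule(sample(1:40, 1))
    write_pulse_events(s, f)
    back <- read_pulse_events(f, total_duration = s$total_duration)
    expect_equal(back$onset, s$onset)
    expect_equal(back$offset, s$offset)
  }
})

test_that("square-wave rendering uses half-open membership and decodes back", {
  s <- pulse_schedule(0, 0.003, total_duration = 0.01)
  w <- render_wave(s, sample_rate = 1000)
  expect_equal(w$samples, c(1, 1, 1, rep(0, 7)))

  empty <- render_wave(pulse_schedule(numeric(0), numeric(0), 0.01), 1000)
  expect_equal(empty$samples, rep(0, 10))

  expect_error(render_wave(s, sample_rate = 500), "666")

  d <- decode_wave(structure(list(samples = c(0, 1, 1, 0), sample_rate = 1000),
                             class = "wave_render"))
  expect_equal(d$onset, 0.001)
  expect_equal(d$offset, 0.003)
  expect_length(decode_wave(structure(list(samples = rep(0, 8), sample_rate = 1000),
                                      class = "wave_render"))$onset, 0)
  d1 <- decode_wave(structure(list(samples = rep(1, 10), sample_rate = 1000),
                              class = "wave_render"))
  expect_equal(d1$onset, 0)
  expect_equal(d1$offset, 0.010)

  expect_error(decode_wave(structure(list(samples = c(0, 0.5), sample_rate = 1000),
                                     class = "wave_render")), "binary")
})

test_that("render/decode round trip displaces every edge by under one sample", {
  set.seed(7)
  for (i in 1:50) {
    s <- random_schedule(sample(1:30, 1))
    r <- 10000
    back <- decode_wave(render_wave(s, sample_rate = r))
    expect_length(back$onset, length(s$onset))
    expect_true(all(abs(back$onset - s$onset) < 1 / r))
    expect_true(all(abs(back$offset - s$offset) < 1 / r))
  }
})

test_that("PCM wave files and TTL event lists round trip", {
  s <- pulse_schedule(c(0.1, 0.25, 0.4), c(0.103, 0.253, 0.403),
                      total_duration = 0.5)
  w <- render_wave(s, sample_rate = 10000)

  wav <- withr::local_tempfile(fileext = ".wav")
  write_wave_file(w, wav)
  back <- read_wave_file(wav)
  expect_equal(back$sample_rate, 10000)
  expect_equal(back$samples, w$samples)

  ttl <- withr::local_tempfile(fileext = ".csv")
  write_ttl_events(s, ttl)
  df <- utils::read.csv(ttl)
  expect_equal(df$state, rep(c(1L, 0L), 3))
  s2 <- read_ttl_events(ttl, total_duration = 0.5)
  expect_equal(s2$onset, s$onset)
  expect_equal(s2$offset, s$offset)
})

test_that("pulse schedule invariants are enforced", {
  expect_error(pulse_schedule(0.1, 0.1, 1), "exceed")
  expect_error(pulse_schedule(c(0, 0.002), c(0.003, 0.005), 1), "overlap")
  expect_error(pulse_schedule(0.9, 1.2, 1), "within")
  expect_error(spike_train(c(0.1, 0.1), 1), "strictly increasing")
})
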