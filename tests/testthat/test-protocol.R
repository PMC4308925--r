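test_that("default electrical train matches the standard protocol", {
  p <- electrical_train_protocol()
  expect_equal(p$n_pulses, 16L)
  expect_equal(p$pulse_width, 2)
  expect_equal(p$frequency, 0.5)
  expect_equal(p$intensity_multiple, 3)
})

test_that("stimulus onsets are evenly spaced at 1000/frequency from 0", {
  expect_equal(stimulus_onsets(electrical_train_protocol()),
               seq(0, 30000, by = 2000))
  expect_equal(stimulus_onsets(electrical_train_protocol(n_pulses = 1)), 0)
  expect_equal(stimulus_onsets(electrical_train_protocol(n_pulses = 3,
                                                         frequency = 1)),
               c(0, 1000, 2000))
  for (f in c(0.25, 0.5, 2, 5)) {
    on <- stimulus_onsets(electrical_train_protocol(n_pulses = 8,
                                                    frequency = f))
    expect_equal(unique(diff(on)), 1000 / f)
  }
})

test_that("protocol invariants are enforced", {
  expect_error(electrical_train_protocol(n_pulses = 0), "n_pulses")
  expect_error(electrical_train_protocol(frequency = 0), "frequency")
  expect_error(electrical_train_protocol(pulse_width = -1), "pulse_width")
})

test_that("latency windows default to a contiguous partition of [0, 800)", {
  w <- latency_windows()
  expect_equal(w$abeta, c(0, 20))
  expect_equal(w$adelta, c(20, 90))
  expect_equal(w$c, c(90, 350))
  expect_equal(w$postdischarge, c(350, 800))
  # no gap, no overlap: each window starts where the previous one ends
  his <- vapply(unclass(w), `[`, numeric(1), 2)
  los <- vapply(unclass(w), `[`, numeric(1), 1)
  expect_equal(unname(his[-4]), unname(los[-1]))
})

test_that("overlapping or gapped windows are rejected", {
  expect_error(latency_windows(abeta = c(0, 25)), "contiguous")
  expect_error(latency_windows(adelta = c(30, 90)), "contiguous")
  expect_error(latency_windows(cband = c(350, 90)), "lo < hi")
})

test_that("natural stimuli validate modality and magnitude sets", {
  expect_equal(natural_stimulus("brush")$duration_s, 10)
  expect_equal(natural_stimulus("von_frey", 8)$magnitude, 8)
  expect_equal(natural_stimulus("heat", 48)$magnitude, 48)
  expect_error(natural_stimulus("von_frey", 10), "protocol set")
  expect_error(natural_stimulus("brush", 5), "no magnitude")
  expect_error(natural_stimulus("heat"), "magnitude required")
  expect_silent(natural_stimulus("von_frey", 10, strict = FALSE))
})

test_that("dose schedules default by route and validate ladders", {
  sp <- dose_schedule("spinal")
  expect_equal(sp$doses, c(10, 50, 100))
  expect_equal(sp$test_minutes, c(10, 30, 50))
  expect_equal(sp$dose_unit, "ug")
  sy <- dose_schedule("systemic")
  expect_equal(sy$doses, c(3, 30))
  ip <- dose_schedule("intraperitoneal")
  expect_equal(ip$test_minutes, c(30, 60))
  expect_error(dose_schedule("spinal", doses = c(50, 10)), "increasing")
  expect_error(dose_schedule("spinal", test_minutes = c(10, 70)), "\\[0, 60\\]")
})

test_that("protocol config round-trips through the flat key=value format", {
  p <- electrical_train_protocol(n_pulses = 8, frequency = 1)
  f <- tempfile(fileext = ".cfg")
  on.exit(unlink(f), add = TRUE)
  write_protocol_config(p, f)
  expect_equal(read_protocol_config(f), p)
  writeLines(c("n_pulses=8", "bogus_key=1"), f)
  expect_error(read_protocol_config(f), "unknown protocol keys")
  writeLines(c("n_pulses 8"), f)
  expect_error(read_protocol_config(f), "line 1")
})
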