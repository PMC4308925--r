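test_that("per-pulse latencies reference the nearest preceding onset", {
  on <- default_onsets()
  rec <- spike_recording("n1", "MIA", on,
                         c(on[1] + 5, on[2] + 150, on[16] + 799.9, 31999),
                         electrical_train_protocol())
  lat <- dorsalhorn:::spike_latencies(rec)
  expect_equal(lat$latency, c(5, 150, 799.9, 31999 - on[16]))
  expect_equal(lat$pulse, c(1L, 2L, 16L, 16L))
  # a spike before the first onset has no reference pulse
  rec2 <- spike_recording("n1", "MIA", c(100, 2100), c(50, 150),
                          electrical_train_protocol(n_pulses = 2))
  lat2 <- dorsalhorn:::spike_latencies(rec2)
  expect_equal(lat2$pulse[1], 0L)          # no reference pulse
  expect_true(is.na(lat2$latency[1]))
  expect_equal(lat2$latency[2], 50)
})

test_that("PSTH bins partition the counting window and sum to total", {
  set.seed(11)
  rec <- random_train()
  h <- build_psth(rec, bin_width = 10)
  expect_equal(nrow(h), 80L)
  expect_equal(h$bin_lo, seq(0, 790, by = 10))
  bc <- band_counts(rec)
  expect_equal(sum(h$count), sum(bc$totals))
  # bin edges are half-open: a spike exactly at 10 ms goes to bin 2
  r <- spike_recording("e", "sham", 0, c(9.999999, 10),
                       electrical_train_protocol(n_pulses = 1))
  h2 <- build_psth(r, bin_width = 10)
  expect_equal(h2$count[1:2], c(1L, 1L))
  expect_error(build_psth(rec, bin_width = 7), "divide 800")
})

test_that("band edges are half-open [lo, hi)", {
  on <- 0
  p1 <- electrical_train_protocol(n_pulses = 1)
  at <- function(t) band_counts(spike_recording("e", "MIA", on, t, p1))$totals
  expect_equal(unname(at(0)), c(1, 0, 0, 0))
  expect_equal(unname(at(19.999)), c(1, 0, 0, 0))
  expect_equal(unname(at(20)), c(0, 1, 0, 0))
  expect_equal(unname(at(90)), c(0, 0, 1, 0))
  expect_equal(unname(at(349.999)), c(0, 0, 1, 0))
  expect_equal(unname(at(350)), c(0, 0, 0, 1))
  expect_equal(unname(at(799.999)), c(0, 0, 0, 1))
  expect_equal(sum(at(800)), 0)   # >= 800 ms: uncounted
})

test_that("ramped fixture gives c_total 136, input 16, wind-up 120", {
  bc <- band_counts(ramped_train())
  expect_equal(unname(bc$totals["c"]), 136)
  expect_equal(unname(bc$per_stimulus[, "c"]), 1:16)
  expect_equal(sum(bc$totals[c("abeta", "adelta", "postdischarge")]), 0)
  expect_equal(input_measure(bc), 16)
  expect_equal(windup_measure(bc), 120)
})

test_that("input scales the first-pulse C count by the pulse count", {
  on <- default_onsets()
  p <- electrical_train_protocol()
  rec <- spike_recording("n", "MIA", on, c(on[1] + c(100, 120, 140)), p)
  expect_equal(input_measure(band_counts(rec)), 48)
  # non-default protocol length
  p8 <- electrical_train_protocol(n_pulses = 8)
  rec8 <- spike_recording("n", "MIA", stimulus_onsets(p8),
                          c(100, 150), p8)
  expect_equal(input_measure(band_counts(rec8)), 16)
})

test_that("wind-up may be negative and can include postdischarge", {
  on <- default_onsets()
  p <- electrical_train_protocol()
  # 5 C spikes on pulse 1, none later: input 80 > c_total 5
  rec <- spike_recording("n", "MIA", on, on[1] + seq(100, 180, by = 20), p)
  bc <- band_counts(rec)
  expect_equal(windup_measure(bc), 5 - 80)
  # postdischarge spikes included only when asked
  rec2 <- spike_recording("n", "MIA", on,
                          c(on[1] + 100, on[3] + c(400, 500, 600)), p)
  bc2 <- band_counts(rec2)
  expect_equal(windup_measure(bc2), 1 - 16)
  expect_equal(windup_measure(bc2, include_postdischarge = TRUE), 4 - 16)
})

test_that("natural evoked count covers the 10 s stimulation window", {
  stim <- natural_stimulus("von_frey", 26)
  rec <- spike_recording("n", "MIA", 0,
                         c(0, 5000, 9999.99, 10000, 12000), stim)
  expect_equal(natural_evoked_count(rec)$evoked_count, 3L)
  br <- spike_recording("n", "sham", 1000, c(500, 1000, 10999, 11000),
                        natural_stimulus("brush"))
  expect_equal(natural_evoked_count(br)$evoked_count, 2L)
})

test_that("summarise_electrical is consistent with its parts", {
  set.seed(7)
  rec <- random_train()
  s <- summarise_electrical(rec)
  bc <- band_counts(rec)
  expect_equal(s$abeta_total, unname(bc$totals["abeta"]))
  expect_equal(s$adelta_total, unname(bc$totals["adelta"]))
  expect_equal(s$c_total, unname(bc$totals["c"]))
  expect_equal(s$pd_total, unname(bc$totals["postdischarge"]))
  expect_equal(s$input, input_measure(bc))
  expect_equal(s$windup, windup_measure(bc))
})

test_that("recording validation rejects malformed inputs", {
  p <- electrical_train_protocol(n_pulses = 2)
  expect_error(spike_recording("n", "MIA", c(2000, 0), c(1, 2), p), "sorted")
  expect_error(spike_recording("n", "MIA", c(0, 2000), c(5, 1), p), "sorted")
  expect_error(spike_recording("n", "bogus", c(0, 2000), 1, p))
  expect_error(spike_recording("n", "MIA", c(0, 2000, 4000), 1, p),
               "one onset per pulse")
})
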