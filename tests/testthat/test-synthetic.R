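test_that("MIA neurones scale the evoked rates by the sensitisation gain", {
  sh <- neurone_params("sham")
  mia <- neurone_params("MIA")
  for (nm in c("mu_abeta", "mu_adelta", "mu_c", "mu_pd", "brush_rate",
               "vf_rate0", "vf_slope", "heat_rmax"))
    expect_equal(mia[[nm]], sh[[nm]] * sh$mia_gain)
  expect_equal(mia$windup_gain, sh$windup_gain)   # wind-up shape unchanged
  expect_error(neurone_params("sham", mu_c = -1), "rates")
})

test_that("natural rates are monotone in stimulus intensity", {
  p <- neurone_params("sham")
  vf <- vapply(c(2, 8, 26, 60), function(g)
    natural_rate(p, natural_stimulus("von_frey", g)), numeric(1))
  expect_true(all(diff(vf) > 0))
  heat <- vapply(c(40, 45, 48), function(t)
    natural_rate(p, natural_stimulus("heat", t)), numeric(1))
  expect_true(all(diff(heat) > 0))
  expect_equal(natural_rate(p, natural_stimulus("brush")), p$brush_rate)
})

test_that("wind-up factor starts at 1 and saturates at 1 + gain", {
  p <- neurone_params("sham", windup_gain = 0.8, windup_tau = 4)
  expect_equal(dorsalhorn:::windup_factor(p, 1), 1)
  f <- dorsalhorn:::windup_factor(p, 1:16)
  expect_true(all(diff(f) > 0))
  expect_lt(max(f), 1.8)
  expect_equal(dorsalhorn:::windup_factor(p, 1e6), 1.8)
})

test_that("inhibition follows a Hill curve gated by the disease state", {
  d <- drug_model(f_max = 0.7, ed50 = 30, hill = 1.5, s_mia = 1, s_sham = 0.1)
  expect_equal(inhibition_fraction(d, 0, "MIA"), 0)
  expect_equal(inhibition_fraction(d, 30, "MIA"), 0.35)     # half of f_max
  expect_equal(inhibition_fraction(d, 30, "sham"), 0.035)   # 10x weaker
  i <- vapply(c(10, 50, 100), inhibition_fraction, numeric(1), drug = d,
              group = "MIA")
  expect_true(all(diff(i) > 0))
  expect_lt(max(i), d$f_max)
})

test_that("simulated electrical trains respect the protocol geometry", {
  set.seed(101)
  p <- neurone_params("MIA")
  rec <- simulate_electrical_train(p)
  expect_s3_class(rec, "spike_recording")
  expect_equal(rec$onsets, default_onsets())
  lat <- dorsalhorn:::spike_latencies(rec)$latency
  expect_true(all(lat >= 0 & lat < 800))
  # inhibition thins the evoked response
  set.seed(101)
  many0 <- replicate(40, sum(band_counts(
    simulate_electrical_train(p, inhibition = 0))$totals))
  many7 <- replicate(40, sum(band_counts(
    simulate_electrical_train(p, inhibition = 0.7))$totals))
  expect_lt(mean(many7), 0.5 * mean(many0))
})

test_that("baseline trials pass the stability screen by construction", {
  for (seed in 1:10) {
    set.seed(seed)
    p <- dorsalhorn:::jitter_params(if (seed %% 2) "MIA" else "sham", 0.15)
    recs <- simulate_timecourse(p, drug_model(), dose_schedule("spinal"))
    q <- quantify_recordings(recs)
    base <- q[q$dose == "predrug", ]
    mat <- do.call(cbind, lapply(split(base, base$measure), function(d)
      d$value[order(d$trial)]))
    mat <- mat[, dorsalhorn:::stability_measures(colnames(mat)), drop = FALSE]
    expect_true(check_baseline_stability(mat)$accepted,
                info = paste("seed", seed))
  }
})

test_that("cohorts have the study layout and label recordings fully", {
  cfg <- cohort_config(seed = 404)
  recs <- simulate_cohort(cfg)
  ids <- unique(vapply(recs, `[[`, "", "neurone_id"))
  expect_equal(sum(grepl("^MIA", ids)), 7)
  expect_equal(sum(grepl("^sham", ids)), 6)
  # per neurone: 3 baselines + 3 doses x 3 minutes electrical trains,
  # each trial with 1 electrical + 8 natural recordings
  expect_equal(length(recs), (7 + 6) * (3 + 9) * 9)
  doses <- unique(vapply(recs, `[[`, "", "dose"))
  expect_setequal(doses, c("predrug", "10", "50", "100"))
})

test_that("behavioural cohorts separate MIA and sham at day 14", {
  cfg <- cohort_config(seed = 11)
  beh <- simulate_behaviour_cohort(cfg)
  expect_setequal(unique(beh$arm), c("sham", "vehicle", "3mg/kg", "30mg/kg"))
  d14 <- beh[beh$timepoint == "day14", ]
  expect_lt(median(d14$pwt50[d14$group == "MIA"]),
            median(d14$pwt50[d14$group == "sham"]))
  expect_gt(mean(d14$acetone_freq[d14$group == "MIA"]),
            mean(d14$acetone_freq[d14$group == "sham"]))
  expect_lt(mean(d14$weight_bearing_ipsi[d14$group == "MIA"]), 50)
  expect_true(all(beh$pwt50 >= 0.4 & beh$pwt50 <= 15))
  expect_true(all(beh$acetone_freq %in% seq(0, 100, by = 20)))
})

test_that("the config refuses to run without a master seed", {
  expect_error(cohort_config(), "seed")
  expect_error(cohort_config(seed = NA), "seed")
  cfg <- cohort_config(seed = 1, route = "systemic")
  expect_equal(cfg$n_mia, 5L)
  expect_equal(cfg$n_sham, 6L)
})
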