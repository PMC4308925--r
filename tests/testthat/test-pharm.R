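test_that("stability screen applies the C-fibre 10% and other 20% thresholds", {
  trials <- cbind(c = c(100, 105, 111), input = c(50, 52, 54))
  st <- check_baseline_stability(trials)
  # C variation: 100*(111-100)/105.333 = 10.44% -> rejected at 10%
  expect_equal(unname(st$variation["c"]), 100 * 11 / mean(c(100, 105, 111)))
  expect_false(st$accepted)
  # input variation 100*4/52 = 7.7% would pass the 20% rule on its own
  expect_lt(st$variation["input"], 20)
  ok <- check_baseline_stability(cbind(c = c(100, 104, 100),
                                       input = c(50, 52, 54)))
  expect_true(ok$accepted)
})

test_that("stability screen uses the last three of many control trials", {
  trials <- cbind(c = c(500, 100, 104, 100))   # wild first trial ignored
  expect_true(check_baseline_stability(trials)$accepted)
  expect_error(check_baseline_stability(cbind(c = c(1, 2))), "3 consecutive")
})

test_that("max_dev rule and zero-mean measures behave as documented", {
  trials <- cbind(c = c(100, 105, 111), pd = c(0, 0, 0))
  st <- check_baseline_stability(trials, rule = "max_dev")
  expect_equal(unname(st$variation["c"]),
               100 * max(abs(c(100, 105, 111) - mean(c(100, 105, 111)))) /
                 mean(c(100, 105, 111)))
  expect_equal(unname(st$variation["pd"]), 0)
  # a nonzero pd trial against a small mean blows up the relative variation
  st2 <- check_baseline_stability(cbind(c = c(100, 101, 100),
                                        pd = c(0, 1, 0)))
  expect_equal(unname(st2$variation["pd"]), 300)
  expect_false(st2$accepted)
  # zero-mean with nonzero spread (possible for signed measures) is Inf
  st3 <- check_baseline_stability(cbind(w = c(-1, 0, 1)))
  expect_equal(unname(st3$variation["w"]), Inf)
  expect_false(st3$accepted)
})

test_that("predrug averaging returns per-measure means of stable trials", {
  trials <- cbind(c = c(100, 104, 100), input = c(48, 50, 52))
  expect_equal(average_predrug(trials), c(c = 101 + 1 / 3, input = 50))
  bad <- cbind(c = c(100, 105, 120))
  expect_error(average_predrug(bad), "stability screen")
  expect_equal(unname(average_predrug(bad, require_stable = FALSE)),
               mean(c(100, 105, 120)))
})

test_that("dose effect picks the maximal deviation, earliest minute on ties", {
  e <- dose_effect(100, c(`10` = 90, `30` = 60, `50` = 80))
  expect_equal(e$minute_at_max, 30)
  expect_equal(e$raw_at_max, 60)
  expect_equal(e$max_pct_change, -40)
  # deviation is absolute: facilitation can win
  e2 <- dose_effect(100, c(`10` = 150, `30` = 70))
  expect_equal(e2$max_pct_change, 50)
  # tie in |deviation| -> earliest minute
  e3 <- dose_effect(100, c(`10` = 120, `30` = 80))
  expect_equal(e3$minute_at_max, 10)
  expect_equal(e3$raw_at_max, 120)
  # unordered names are sorted by minute first
  e4 <- dose_effect(100, c(`50` = 99, `10` = 50, `30` = 98))
  expect_equal(e4$minute_at_max, 10)
})

test_that("zero baseline reports raw change only, with percentage undefined", {
  e <- dose_effect(0, c(`10` = 3, `30` = 1))
  expect_false(e$pct_defined)
  expect_true(is.na(e$max_pct_change))
  expect_equal(e$raw_change, 3)
  expect_output(print(e), "baseline 0")
})

test_that("group dose-response table is mean +/- SEM of raw maxima", {
  effects <- list(
    dose_effect(100, c(`10` = 80, `30` = 60), measure = "c", dose = 10),
    dose_effect(120, c(`10` = 100, `30` = 90), measure = "c", dose = 10),
    dose_effect(100, c(`10` = 50, `30` = 40), measure = "c", dose = 50),
    dose_effect(120, c(`10` = 60, `30` = 55), measure = "c", dose = 50))
  tab <- assemble_dose_response(effects)
  expect_equal(tab$dose, c("baseline", "10", "50"))
  expect_equal(tab$n, c(2L, 2L, 2L))
  expect_equal(tab$mean, c(110, 75, 47.5))
  expect_equal(tab$sem[2], sd(c(60, 90)) / sqrt(2))
  # baseline row averages the per-neurone baselines once per dose ladder
  expect_equal(tab$mean[1], mean(c(100, 120)))
})
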