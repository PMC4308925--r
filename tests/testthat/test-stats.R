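test_that("exact Mann-Whitney matches direct enumeration, ties included", {
  set.seed(21)
  cases <- list(
    list(x = c(1, 2, 3), y = c(4, 5, 6)),
    list(x = c(1, 5, 9), y = c(2, 6, 10, 12)),
    list(x = c(1, 1, 2), y = c(1, 2, 2, 3)),          # heavy ties
    list(x = rnorm(5), y = rnorm(6)),
    list(x = c(2, 2, 2), y = c(2, 2, 2)))             # all tied
  for (cs in cases) {
    got <- mann_whitney_u(cs$x, cs$y, mode = "exact")
    expect_equal(got$p_value, enum_mw_p(cs$x, cs$y), info = "exact vs oracle")
    expect_equal(got$mode_used, "exact")
  }
})

test_that("complete separation at n = 3 vs 3 gives the exact p of 0.1", {
  t <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12), mode = "exact")
  expect_equal(t$p_value, 2 / choose(6, 3))
  expect_equal(t$statistic, 0)
})

test_that("auto mode switches at the exact-threshold total n", {
  x <- 1:7; y <- 8:14
  expect_equal(mann_whitney_u(x, y)$mode_used, "exact")
  expect_equal(mann_whitney_u(c(x, 20), y)$mode_used, "approximate")
  expect_equal(mann_whitney_u(c(x, 20), y, mode = "exact")$mode_used, "exact")
})

test_that("approximate Mann-Whitney tracks wilcox.test without ties", {
  set.seed(33)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  got <- mann_whitney_u(x, y, mode = "approximate")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$statistic, unname(ref$statistic))
})

test_that("Kruskal-Wallis wraps the tie-corrected H against chi-squared", {
  g <- list(a = c(1, 3, 5), b = c(2, 4, 6), c = c(10, 11, 12))
  got <- kruskal_wallis(g)
  ref <- stats::kruskal.test(unlist(g), factor(rep(1:3, each = 3)))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  expect_equal(got$df, 2)
  # degenerate all-identical input
  same <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(kruskal_wallis(list(1:3, 4:6)), "3 groups")
})

test_that("Dunn z matches a hand-computed value and Bonferroni clamps at 1", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  out <- dunn_posttest(g)
  # no ties: z_ab = (2-5)/sqrt((9*10/12)*(2/3))
  expect_equal(out$z[out$group1 == "a" & out$group2 == "b"],
               (2 - 5) / sqrt(9 * 10 / 12 * (2 / 3)))
  expect_equal(out$p_adjusted, pmin(1, out$p_raw * 3))
  expect_true(all(out$p_adjusted <= 1))
  # restricted comparison set divides by its own size
  two <- dunn_posttest(g, comparisons = list(c("a", "b")))
  expect_equal(two$p_adjusted, pmin(1, two$p_raw * 1))
  expect_error(dunn_posttest(g, comparisons = list(c("a", "zz"))), "unknown")
})

test_that("Dunn tie correction uses T / (12(N-1))", {
  g <- list(a = c(1, 1, 2), b = c(2, 3, 3), c = c(4, 4, 4))
  out <- dunn_posttest(g, comparisons = list(c("a", "c")))
  r <- rank(unlist(g))
  ties <- table(r); tt <- sum(ties^3 - ties) / (12 * 8)
  v <- (9 * 10 / 12 - tt) * (2 / 3)
  z_hand <- (mean(r[1:3]) - mean(r[7:9])) / sqrt(v)
  expect_equal(out$z, z_hand)
})

test_that("one-way RM-ANOVA agrees with the direct sums-of-squares oracle", {
  set.seed(5)
  mat <- matrix(rnorm(8 * 4, mean = rep(c(0, 1, 2, 1.5), each = 8)), 8, 4)
  out <- rm_anova(long_from_matrix(mat), design = "one_way")
  oracle <- direct_rm_anova_1w(mat)
  expect_equal(out$F, oracle$F)
  expect_equal(out$df1, oracle$df1)
  expect_equal(out$df2, oracle$df2)
  expect_equal(out$p_value, oracle$p)
  expect_match(out$caveat, "sphericity")
})

test_that("RM-ANOVA rejects unbalanced tables and flags degenerate data", {
  d <- long_from_matrix(matrix(rnorm(12), 4, 3))
  expect_error(rm_anova(d[-1, ], design = "one_way"), "balanced")
  flat <- long_from_matrix(matrix(5, 4, 3))
  out <- rm_anova(flat, design = "one_way")
  expect_true(out$degenerate)
  expect_true(is.na(out$p_value))
})

test_that("two-way RM-ANOVA returns all three within-subject effects", {
  set.seed(9)
  d <- expand.grid(subject = paste0("s", 1:6), factor1 = c("b", "p1", "p2"),
                   factor2 = c("low", "high"), stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d)) + ifelse(d$factor2 == "high", 2, 0)
  out <- rm_anova(d, design = "two_way")
  expect_setequal(out$effect, c("factor1", "factor2", "factor1:factor2"))
  expect_true(all(out$df1 %in% c(2, 1)))
  expect_true(all(is.finite(out$F)))
})

test_that("Bonferroni paired t multiplies stats::t.test p-values", {
  set.seed(13)
  mat <- matrix(rnorm(6 * 3, mean = rep(c(0, 1, 3), each = 6)), 6, 3,
                dimnames = list(NULL, c("baseline", "d10", "d50")))
  out <- bonferroni_paired_t(long_from_matrix(mat))
  expect_equal(nrow(out), 2)
  ref <- stats::t.test(mat[, "baseline"], mat[, "d10"], paired = TRUE)
  i <- which(out$level2 == "d10")
  expect_equal(out$p_raw[i], ref$p.value)
  expect_equal(out$p_adjusted, pmin(1, out$p_raw * 2))
})
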