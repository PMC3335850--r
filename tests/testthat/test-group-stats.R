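test_that("2x2 chi-square matches a brute-force expected-count oracle", {
  # independent oracle: expected counts from margins, sum (o - e)^2 / e
  oracle <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  set.seed(17)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    m <- matrix(tabulate(sample(1:4, n, replace = TRUE), 4), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(chi_square_2x2(m)$statistic, oracle(m), tolerance = 1e-12)
  }
  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 7), 2, byrow = TRUE)),
               "margin")
})

test_that("published contingency rows reproduce to printed precision", {
  # smoking 18/21 vs 46/11; suicide 0/71 vs 15/57; sex 55/16 vs 50/22;
  # hemisphere 30/41 vs 37/35
  expect_equal(round(chi_square_2x2(c(18, 21, 46, 11))$statistic, 3), 12.437)
  expect_equal(round(chi_square_2x2(c(0, 71, 15, 57))$statistic, 3), 16.525)
  expect_equal(round(chi_square_2x2(c(55, 16, 50, 22))$statistic, 3), 1.179)
  expect_equal(round(chi_square_2x2(c(30, 41, 37, 35))$statistic, 3), 1.198)
})

test_that("pooled t agrees with t.test on raw data and with summaries", {
  set.seed(23)
  x <- rnorm(14, 1, 2); y <- rnorm(9, 0, 2)
  mine <- pooled_t_test(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter))
  # summary-statistic route gives the same answer as the raw route
  s <- pooled_t_test(n1 = 14, mean1 = mean(x), sd1 = sd(x),
                     n2 = 9, mean2 = mean(y), sd2 = sd(y))
  expect_equal(s$statistic, mine$statistic, tolerance = 1e-12)
  # printed PMI comparison: t(141) = -1.267 (the summaries themselves are
  # rounded to 2 dp, so agreement holds to ~0.001)
  pmi <- pooled_t_test(n1 = 71, mean1 = 27.04, sd1 = 12.15,
                       n2 = 72, mean2 = 29.89, sd2 = 14.63)
  expect_equal(pmi$statistic, -1.267, tolerance = 0.001)
  expect_equal(pmi$df, 141)
  # identical summaries give t = 0, p = 1
  eq <- pooled_t_test(n1 = 10, mean1 = 5, sd1 = 1, n2 = 12, mean2 = 5, sd2 = 1)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_error(pooled_t_test(n1 = 5, mean1 = 1, sd1 = 0,
                             n2 = 5, mean2 = 2, sd2 = 0), "pooled variance")
})

test_that("one-tailed p is p/2 on a match and 1 - p/2 on a mismatch", {
  set.seed(29)
  x <- rnorm(20, 1); y <- rnorm(20, 0)
  two <- pooled_t_test(x, y, tails = "two")
  match <- pooled_t_test(x, y, tails = "one", predicted_direction = "greater")
  miss <- pooled_t_test(x, y, tails = "one", predicted_direction = "less")
  expect_equal(match$p_value, two$p_value / 2, tolerance = 1e-12)
  expect_equal(miss$p_value, 1 - two$p_value / 2, tolerance = 1e-12)
})

test_that("Mann-Whitney U matches brute-force enumeration", {
  # complete separation
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  # interleaved case: reported U is min(U1, n1 n2 - U1)
  u <- mann_whitney_u(c(1, 3, 5), c(2, 4, 6))
  expect_equal(u$statistic, min(brute_u_pairs(c(2, 4, 6), c(1, 3, 5)),
                                brute_u_pairs(c(1, 3, 5), c(2, 4, 6))))
  expect_equal(u$statistic, 3)
  # exact p equals full enumeration over several random small instances
  set.seed(31)
  for (i in 1:12) {
    x <- sample(1:100, sample(3:7, 1))
    y <- sample(101:200, sample(3:7, 1)) - 100.5  # no ties with x
    expect_equal(mann_whitney_u(x, y)$p_value, brute_u_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney normal approximation tracks the exact p", {
  # at n1 = n2 = 8 without ties, the continuity-corrected approximation
  # stays within ~0.011 of exact enumeration uniformly over U (the bound
  # is a property of the approximation; exhaustive over instances here)
  set.seed(37)
  worst <- 0
  for (i in 1:40) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    exact <- mann_whitney_u(x, y, p_method = "exact")$p_value
    approx <- mann_whitney_u(x, y, p_method = "approximate")$p_value
    worst <- max(worst, abs(exact - approx))
  }
  expect_lte(worst, 0.011)
})

test_that("Mann-Whitney handles ties, symmetry and degenerate input", {
  # two identical groups: symmetric, p near 1
  x <- c(1, 2, 3, 4, 5)
  u <- mann_whitney_u(x, x)
  expect_equal(u$statistic, 12.5)
  expect_gt(u$p_value, 0.9)
  expect_warning(res <- mann_whitney_u(rep(1, 5), rep(1, 6)), "tied")
  expect_equal(res$effect_size_r, 0)
  # agreement with wilcox.test on tied data (normal approximation)
  set.seed(41)
  xs <- sample(1:5, 30, replace = TRUE)
  ys <- sample(2:6, 30, replace = TRUE)
  ref <- suppressWarnings(wilcox.test(xs, ys, correct = TRUE, exact = FALSE))
  expect_equal(mann_whitney_u(xs, ys)$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("effect-size conversions reproduce printed values and identities", {
  expect_equal(round(effect_size_from_t(2.656, 139), 2), 0.22)
  expect_equal(round(effect_size_from_t(2.74, 61), 2), 0.33)
  expect_equal(effect_size_from_t(0, 100), 0)
  expect_equal(effect_size_from_z(1.96, 100), 0.196)
  expect_equal(effect_size_from_chi2(4, 100), 0.2)
  expect_equal(effect_size_from_chi2(0, 10), 0)
  # asymptotic agreement: sqrt(t^2/(t^2+df)) ~ |t|/sqrt(N) for large df
  expect_equal(effect_size_from_t(2.1, 1e6), effect_size_from_z(2.1, 1e6),
               tolerance = 1e-5)
})

test_that("correlation screen: hand-ranked Spearman, ties, missing data", {
  # hand computation: d = (-2, 1, 1, -1, 1), d^2 = 8,
  # rho = 1 - 6 * 8 / (5 * 24) = 0.6
  s <- correlation_screen(data.frame(g = c(1, 2, 3, 4, 5)),
                          data.frame(v = c(3, 1, 2, 5, 4)))
  expect_equal(unname(s$r["g", "v"]), 0.6)
  # perfect monotone pair
  s2 <- correlation_screen(data.frame(g = c(1, 5, 20)),
                           data.frame(v = c(2, 30, 31)))
  expect_equal(unname(s2$r["g", "v"]), 1)
  # constant covariate reported as missing
  s3 <- correlation_screen(data.frame(g = rnorm(10)),
                           data.frame(v = rep(2, 10)))
  expect_true(is.na(s3$r["g", "v"]))
  # pairwise-complete handling
  x <- c(1:9, NA); y <- c(NA, 2:10)
  s4 <- correlation_screen(data.frame(g = x), data.frame(v = y))
  expect_equal(unname(s4$r["g", "v"]), 1)
})

test_that("two-way ANOVA matches a direct sums-of-squares oracle", {
  # balanced 3 x 4 with known additive effects
  set.seed(43)
  d <- expand.grid(a = factor(1:3), b = factor(1:4), rep = 1:5)
  eff_a <- c(0, 1, 2)[d$a]; eff_b <- c(0, 0.5, 1, 1.5)[d$b]
  d$y <- 10 + eff_a + eff_b + rnorm(nrow(d), 0, 0.5)
  res <- two_way_anova(d$y, d$a, d$b)
  # direct oracle for the balanced case: classical partitioned SS
  gm <- mean(d$y)
  ssa <- sum(tapply(d$y, d$a, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(d$y, d$b, function(v) length(v) * (mean(v) - gm)^2))
  cell <- tapply(d$y, list(d$a, d$b), mean)
  ssab <- 5 * sum((sweep(sweep(cell, 1, tapply(d$y, d$a, mean)), 2,
                         tapply(d$y, d$b, mean)) + gm)^2)
  sse <- sum((d$y - ave(d$y, d$a, d$b))^2)
  dfe <- nrow(d) - 12
  f_oracle <- c(ssa / 2, ssb / 3, ssab / 6) / (sse / dfe)
  expect_equal(res$table$F, f_oracle, tolerance = 1e-10)
  expect_equal(res$table$df2, rep(dfe, 3))
})

test_that("two-way ANOVA degenerate and invariance properties hold", {
  # identical cell means in a balanced 2x2: all F = 0
  d <- expand.grid(a = factor(1:2), b = factor(1:2), rep = 1:4)
  d$y <- as.numeric(d$rep)  # every cell holds 1,2,3,4: identical cell means
  res <- two_way_anova(d$y, d$a, d$b)
  expect_equal(res$table$F, rep(0, 3), tolerance = 1e-12)
  expect_error(two_way_anova(rnorm(6), factor(rep(1, 6)),
                             factor(rep(1:2, 3))), "2 levels")
  # relabelling one factor's levels leaves the other factor's F unchanged
  set.seed(47)
  d2 <- expand.grid(a = factor(1:2), b = factor(1:3), rep = 1:4)
  d2$y <- rnorm(nrow(d2)) + as.numeric(d2$a)
  f_before <- two_way_anova(d2$y, d2$a, d2$b)$table
  b_relab <- factor(c("3", "1", "2")[d2$b])
  f_after <- two_way_anova(d2$y, d2$a, b_relab)$table
  expect_equal(f_before$F[f_before$term == "a"],
               f_after$F[f_after$term == "a"], tolerance = 1e-12)
})

test_that("one-sample t: hand value, identity and antisymmetry", {
  r <- one_sample_t(c(1, 2, 3), mu0 = 0)
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(one_sample_t(c(4, 5, 6, 7), mu0 = 5.5)$statistic, 0)
  set.seed(53)
  v <- rnorm(10, 2)
  expect_equal(one_sample_t(v, 1)$statistic,
               -one_sample_t(2 - v, 1)$statistic, tolerance = 1e-12)
  expect_error(one_sample_t(rep(2, 5), 0), "zero standard deviation")
})

test_that("tidy_comparisons collects results into one row per test", {
  tab <- tidy_comparisons(list(
    pmi = pooled_t_test(n1 = 71, mean1 = 27.04, sd1 = 12.15,
                        n2 = 72, mean2 = 29.89, sd2 = 14.63),
    sex = chi_square_2x2(c(55, 16, 50, 22))))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("test", "statistic", "p_value", "effect_size_r")
                  %in% names(tab)))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
})
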