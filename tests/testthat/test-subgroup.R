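test_that("threshold is median + 1.25 IQR under linear interpolation", {
  # values 1..8: median 4.5, Q1 2.75, Q3 6.25 -> T = 4.5 + 1.25 * 3.5
  expect_equal(high_expression_threshold(1:8), 8.875)
  expect_equal(high_expression_threshold(rep(4, 10)), 4)
  # affine equivariance: T(a x + b) = a T(x) + b for a > 0
  set.seed(61)
  x <- rlnorm(40)
  expect_equal(high_expression_threshold(3 * x + 2),
               3 * high_expression_threshold(x) + 2, tolerance = 1e-12)
  expect_error(high_expression_threshold(c(1, 2, 3)), ">= 4")
  # the SPSS-style weighted-average convention is available and differs:
  # 1..9 -> Q1/Q3 are 3/7 (type 7) but 2.5/7.5 (type 6)
  expect_equal(high_expression_threshold(1:9), 5 + 1.25 * 4)
  expect_equal(high_expression_threshold(1:9, qtype = 6), 5 + 1.25 * 5)
})

test_that("iterative core trimming removes exactly a planted separated tail", {
  set.seed(67)
  core <- rnorm(60, 1, 0.4)
  planted <- 1 + 8 * 0.4 + c(0.0, 0.1, 0.2, 0.3, 0.4)
  res <- iterative_normal_core(c(core, planted))
  expect_equal(sort(res$removed), sort(planted))
  # removal order is descending from the maximum
  expect_equal(res$removed, sort(planted, decreasing = TRUE))
  expect_equal(res$n, 60)
  expect_true(res$converged)
  expect_gt(res$ks_p, 0.05)
})

test_that("core trimming rarely touches genuinely normal samples", {
  removed <- vapply(1:200, function(s) {
    set.seed(s)
    length(iterative_normal_core(rnorm(60))$removed)
  }, numeric(1))
  expect_gte(mean(removed <= 1), 0.80)
})

test_that("core trimming never removes a value below the current mean", {
  for (s in 1:20) {
    set.seed(s)
    x <- c(rnorm(40), rlnorm(10, 1, 0.8))  # right-skewed contamination
    res <- iterative_normal_core(x)
    # every removed value was the maximum of a superset of the final core,
    # so none can lie below the surviving core (or any current mean)
    if (length(res$removed))
      expect_true(all(res$removed >= max(res$values)))
  }
  expect_error(iterative_normal_core(rep(1, 10)), "constant")
  expect_error(iterative_normal_core(rnorm(3)), "at least 5")
})

test_that("SD distance reproduces the printed 5-SD arithmetic", {
  # flagged mean 3.053 against core 0.8919 +/- 0.4308 -> 5.02 SD
  expect_equal(round(sd_distance(3.053, c(0.8919, 0.4308)), 2), 5.02)
  expect_equal(sd_distance(c(2, 4), list(mean = 3, sd = 1)), 0)
  # affine invariance
  set.seed(71)
  x <- rnorm(30); fl <- x + 4
  d0 <- sd_distance(fl, list(mean = mean(x), sd = sd(x)))
  d1 <- sd_distance(5 * fl - 2, list(mean = 5 * mean(x) - 2, sd = 5 * sd(x)))
  expect_equal(d0, d1, tolerance = 1e-12)
  expect_error(sd_distance(1, c(0, 0)), "core SD")
  expect_error(sd_distance(numeric(0), c(0, 1)), "no flagged")
})

test_that("classification and association match hand arithmetic", {
  # constructed 2x2: 9/71 controls vs 22/72 cases flagged
  tab <- matrix(c(9, 62, 22, 50), 2, byrow = TRUE)
  rr <- (22 / 72) / (9 / 71)
  expect_equal(round(rr, 2), 2.41)
  a <- chi_square_2x2(tab)
  expect_equal(a$statistic,
               {e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
                sum((tab - e)^2 / e)}, tolerance = 1e-12)
})

test_that("the full high_expressor fit is consistent across modules", {
  set.seed(73)
  n_ctrl <- 71; n_case <- 72
  grp <- rep(c("control", "schizophrenia"), c(n_ctrl, n_case))
  sub <- runif(length(grp)) < ifelse(grp == "control", 0.13, 0.32)
  vals <- rnorm(length(grp), 1, 0.4) + ifelse(sub, 5 * 0.4, 0)
  fit <- high_expressor(vals, grp, control = "control")
  # threshold computed from controls only
  expect_equal(fit$threshold,
               high_expression_threshold(vals[grp == "control"]))
  # association equals chi_square_2x2 on the induced table
  expect_equal(fit$association$statistic,
               chi_square_2x2(fit$table)$statistic, tolerance = 1e-12)
  # risk ratio is the prevalence ratio of the flag
  expect_equal(fit$risk_ratio,
               mean(vals[grp != "control"] > fit$threshold) /
                 mean(vals[grp == "control"] > fit$threshold))
  # formula interface agrees with the default method
  d <- data.frame(rq = vals, group = grp)
  fit2 <- high_expressor(rq ~ group, d, control = "control")
  expect_equal(fit2$threshold, fit$threshold)
  expect_equal(fit2$table, fit$table)
  # methods run
  expect_output(print(fit), "High-expressor")
  expect_output(print(summary(fit)), "2x2 table")
  expect_named(coef(fit), c("threshold", "core_mean", "core_sd",
                            "sd_distance", "risk_ratio", "odds_ratio"))
  expect_equal(levels(predict(fit)), c("normal", "high"))
  expect_equal(sum(predict(fit) == "high"), sum(fit$flags))
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), length(vals))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("planted subgroups are recovered with high sensitivity", {
  # the published geometry: shift 5 core SD, prevalence 0.13 vs 0.32,
  # n = 71/72 per replicate
  set.seed(79)
  hits <- replicate(100, {
    grp <- rep(c("control", "case"), c(71, 72))
    sub <- runif(143) < ifelse(grp == "control", 0.13, 0.32)
    vals <- rnorm(143, 0, 1) + ifelse(sub, 5, 0)
    fit <- suppressWarnings(high_expressor(vals, grp, control = "control"))
    c(sens = if (any(sub)) mean(fit$flags[sub]) else NA,
      reject = !is.null(fit$association) && fit$association$p_value <= 0.05)
  })
  expect_gt(mean(hits["sens", ], na.rm = TRUE), 0.95)
  # the association test rejects in the majority of replicates
  expect_gt(mean(hits["reject", ]), 0.5)
})

test_that("flagged fraction recovers prevalence within the binomial CI", {
  set.seed(83)
  n <- 600
  grp <- rep(c("control", "case"), each = n / 2)
  p_case <- 0.3
  sub <- runif(n) < ifelse(grp == "control", 0.13, p_case)
  vals <- rnorm(n) + ifelse(sub, 5, 0)
  fit <- high_expressor(vals, grp, control = "control")
  flagged_frac <- mean(fit$flags[grp == "case"])
  ci <- flagged_frac + c(-1.96, 1.96) *
    sqrt(flagged_frac * (1 - flagged_frac) / (n / 2))
  expect_gte(p_case, ci[1]); expect_lte(p_case, ci[2])
})

test_that("type-I behaviour on pure normal data matches the tail geometry", {
  # for a standard normal, P(Z > median + 1.25 IQR) = P(Z > 1.25 * 1.349)
  p_tail <- pnorm(1.25 * (qnorm(0.75) - qnorm(0.25)), lower.tail = FALSE)
  set.seed(89)
  fracs <- replicate(150, {
    grp <- rep(c("control", "case"), each = 70)
    vals <- rnorm(140)
    fit <- suppressWarnings(high_expressor(vals, grp, control = "control"))
    c(frac = mean(fit$flags),
      reject = !is.null(fit$association) && fit$association$p_value <= 0.05)
  })
  expect_lt(abs(mean(fracs["frac", ]) - p_tail), 0.01)
  # under exchangeable groups the association rejects at about alpha
  expect_lt(mean(fracs["reject", ]), 0.12)
})

test_that("degenerate classifications warn rather than fail", {
  grp <- rep(c("control", "case"), each = 30)
  set.seed(97)
  vals <- pmin(rnorm(60), 1)  # censor the upper tail below the threshold
  expect_warning(high_expressor(vals, grp, control = "control"),
                 "no sample exceeds")
  expect_error(high_expressor(rnorm(10), rep("g", 10), control = "g"),
               "no case group")
})
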