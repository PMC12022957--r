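test_that("sample summaries match hand computation and gate normality", {
  s <- summarize_sample(c(1, 2, 3, 4, 5))
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2.5), tolerance = 1e-12)
  expect_equal(s$median, 3)
  expect_equal(s$ci95_low, 3 - qt(0.975, 4) * sqrt(2.5) / sqrt(5),
               tolerance = 1e-12)
  expect_true(s$ci95_low <= s$mean && s$mean <= s$ci95_high)
  expect_true(s$iqr_low <= s$median && s$median <= s$iqr_high)
  # constant sample: degenerate CI at the mean
  sc <- summarize_sample(rep(7, 10))
  expect_equal(sc$sd, 0)
  expect_equal(c(sc$ci95_low, sc$ci95_high), c(7, 7))
  expect_error(summarize_sample(3), "at least 2")
  # the gate agrees with Shapiro-Wilk directly
  set.seed(11)
  x <- rexp(40)
  expect_identical(summarize_sample(x)$distribution_normal,
                   stats::shapiro.test(x)$p.value > 0.05)
})

test_that("Mann-Whitney U equals the brute-force pairwise count on small samples", {
  set.seed(42)
  for (i in 1:30) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    # mix of continuous and tied integer samples
    if (i %% 2 == 0) {
      x <- sample(1:5, nx, replace = TRUE); y <- sample(1:5, ny, replace = TRUE)
    } else {
      x <- rnorm(nx); y <- rnorm(ny)
    }
    res <- mann_whitney_u(x, y)
    expect_equal(res$U, brute_force_u(x, y))
    # complementarity: U_x + U_y = n_x * n_y
    expect_equal(res$U + mann_whitney_u(y, x)$U, nx * ny)
  }
})

test_that("Mann-Whitney behaves at the symmetric and extreme configurations", {
  x <- c(1, 2, 3, 4)
  res <- mann_whitney_u(x, x)
  expect_equal(res$U, length(x)^2 / 2)
  expect_gt(res$p, 0.9)
  res2 <- mann_whitney_u(c(10, 11, 12, 13, 14), c(1, 2, 3, 4, 5))
  expect_equal(res2$U, 25)
  expect_lt(res2$p, 0.01)
  expect_error(mann_whitney_u(numeric(), 1:3), "nonempty")
})

test_that("exact and approximate Mann-Whitney p-values agree for moderate n", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10, 0.3)
    p_exact <- mann_whitney_u(x, y)$p   # 100 pairs, no ties -> exact
    p_approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("chi-square matches the direct O-E formula and flags sparse cells", {
  tab <- matrix(c(9, 17, 1, 27), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_oracle <- sum((tab - expected)^2 / expected)
  res <- chi2_test(9, 17, 1, 27)
  expect_equal(res$statistic, stat_oracle, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_true(res$expected_lt5)
  # proportional table: statistic 0, p = 1
  res0 <- chi2_test(10, 20, 20, 40)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  # the chronotropic-insufficiency table is significant without correction
  expect_lt(chi2_test(6, 20, 1, 27)$p, 0.05)
  expect_error(chi2_test(0, 0, 3, 5), "marginal")
  # Yates correction is available and only shrinks the statistic
  expect_lt(chi2_test(9, 17, 1, 27, correct = TRUE)$statistic, stat_oracle)
})

test_that("the paired signed-rank test matches exhaustive enumeration", {
  set.seed(13)
  for (i in 1:10) {
    before <- rnorm(8, 50, 10)
    after <- before + rnorm(8, 1, 5)
    res <- wilcoxon_paired(before, after)
    oracle <- brute_force_signed_rank(after - before)
    expect_equal(res$statistic, oracle$statistic)
    expect_equal(res$p, oracle$p, tolerance = 1e-12)
  }
})

test_that("degenerate and one-sided paired configurations behave as stated", {
  x <- c(3, 5, 8, 13)
  res <- wilcoxon_paired(x, x)
  expect_true(res$degenerate)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  res2 <- wilcoxon_paired(x, x + c(1, 2, 3, 4))
  expect_false(res2$degenerate)
  expect_equal(res2$statistic, 4 * 5 / 2)  # all ranks positive
  expect_equal(res2$p, 2 / 2^4)            # one-sided extreme, doubled
  expect_error(wilcoxon_paired(1:3, 1:4), "equal length")
})

test_that("mean percentage change divides by the case mean", {
  expect_equal(mean_percentage_change(641, 702), 100 * (641 - 702) / 641)
  expect_equal(round(mean_percentage_change(641, 702)), -10)
  expect_equal(mean_percentage_change(5, 5), 0)
  expect_equal(mean_percentage_change(-11, 12), 100 * (-23) / (-11))
  expect_error(mean_percentage_change(0, 5), "zero case mean")
})

test_that("odds ratios invert under row swap and honor the zero-cell policy", {
  res <- odds_ratio(9, 17, 1, 27)
  expect_equal(res$or, 9 * 27 / 17)
  expect_false(res$corrected)
  swapped <- odds_ratio(1, 27, 9, 17)
  expect_equal(swapped$or, 1 / res$or, tolerance = 1e-12)
  expect_true(res$ci95_low < res$or && res$or < res$ci95_high)
  expect_equal(odds_ratio(10, 20, 5, 10)$or, 1)
  expect_error(odds_ratio(0, 26, 3, 25), "zero cell")
  hal <- odds_ratio(0, 26, 3, 25, zero_cell_policy = "haldane")
  expect_true(hal$corrected)
  expect_equal(hal$or, (0.5 * 25.5) / (26.5 * 3.5))
})

test_that("Hedges' g applies the small-sample shrinkage and labels magnitudes", {
  res <- hedges_g(641, 57, 26, 702, 60, 28)
  expect_equal(round(res$g, 3), -1.026)
  expect_identical(res$label, "large")
  # antisymmetry under group swap
  expect_equal(hedges_g(702, 60, 28, 641, 57, 26)$g, -res$g, tolerance = 1e-12)
  # shrinkage toward zero: |g| < |d| for all finite n
  for (n in c(2, 5, 50, 500)) {
    r <- hedges_g(10, 4, n, 8, 4, n)
    expect_lt(abs(r$g), abs(r$d))
  }
  expect_equal(hedges_g(5, 1, 10, 5, 1, 10)$g, 0)
  expect_identical(hedges_g(5, 1, 10, 5, 1, 10)$label, "small")
  expect_identical(effect_label(c(0.1, 0.5, 1.0, 1.5)),
                   c("small", "medium", "large", "very_large"))
  expect_error(hedges_g(5, 0, 10, 5, 0, 10), "pooled SD")
})

test_that("the sample-size plan reproduces its closed form and scaling law", {
  plan <- sample_size(1.96, 1.28, r = 1, s = 50, d = 31, attrition = 0)
  expect_equal(plan$raw_n, 2 * (1.96 + 1.28)^2 * 2500 / 961, tolerance = 1e-12)
  expect_equal(plan$n_per_group, 27)
  expect_equal(plan$n_total, 54)
  expect_equal(plan$n_revised, 54)
  plan10 <- sample_size(1.96, 1.28, r = 1, s = 50, d = 31, attrition = 0.10)
  expect_equal(plan10$n_revised, 60)
  # doubling the detectable difference quarters the raw size
  plan2 <- sample_size(1.96, 1.28, r = 1, s = 50, d = 62)
  expect_equal(plan2$raw_n, plan$raw_n / 4, tolerance = 1e-12)
  expect_error(sample_size(1.96, 1.28, 1, 50, 0), "infinite")
  # unequal allocation keeps n_case = r * n_control (up to flooring)
  plan_r2 <- sample_size(1.96, 1.28, r = 2, s = 50, d = 31)
  expect_equal(plan_r2$n_case, floor(2 * plan_r2$raw_n / 3))
})
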