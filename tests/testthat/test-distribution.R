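test_that("Anderson-Darling normality test behaves across sample shapes", {
  set.seed(101)
  x <- rnorm(500)
  expect_gt(ad_normality(x)$p_value, 0.05)

  # affine invariance of the statistic
  expect_equal(ad_normality(3 * x - 7)$a_squared, ad_normality(x)$a_squared,
               tolerance = 1e-10)

  set.seed(102)
  skewed <- rexp(500)
  expect_lt(ad_normality(skewed)$p_value, 0.01)

  expect_error(ad_normality(rep(1, 20)), "constant")
  expect_error(ad_normality(rnorm(5)), "at least 8")
})

test_that("Johnson transformation normalises skewed samples monotonically", {
  set.seed(11)
  x <- rlnorm(200)
  fit <- johnson_transform(x)
  expect_true(fit$family %in% c("SB", "SL", "SU"))
  expect_gt(fit$selection_score, 0.05)
  expect_gt(ad_normality(fit$transformed)$p_value, 0.05)
  # strictly increasing: ranks (hence order statistics) preserved
  expect_equal(rank(fit$transformed), rank(x))
  ord <- sort(sample(length(x), 50))
  expect_true(all(diff(fit$transformed[order(x)]) >= 0))

  # an already-normal sample may keep the identity; score never worsens
  set.seed(12)
  z <- rnorm(150)
  fitz <- johnson_transform(z)
  expect_gte(fitz$selection_score, ad_normality(z)$p_value)

  expect_error(johnson_transform(rnorm(5)), "at least 10")
  expect_error(johnson_transform(rep(2, 30)), "constant")
})

test_that("one-sample t-test matches closed forms", {
  r0 <- one_sample_t(c(-1, 0, 1), 0)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)

  r <- one_sample_t(c(1, 2, 3), 0)
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(r$df, 2)

  x <- c(2.5, 3.5, 9, 1)
  expect_equal(one_sample_t(x, mean(x))$t, 0, tolerance = 1e-12)
  expect_error(one_sample_t(rep(4, 6)), "constant")
})

test_that("one-proportion sample size and power follow the normal approximation", {
  expect_equal(sample_size_one_proportion(0.5, 0.54), 1225L)
  expect_equal(sample_size_one_proportion(0.5, 0.46), 1225L)  # symmetry about 0.5
  expect_equal(sample_size_one_proportion(0.5, 0.60), 194L)
  expect_error(sample_size_one_proportion(0.5, 0.5), "differ")

  expect_gte(power_one_proportion(0.5, 0.54, 1225), 0.80)
  expect_equal(power_one_proportion(0.5, 0.54, 1e7), 1, tolerance = 1e-9)
  expect_equal(power_one_proportion(0.5, 0.5, 500), 0.05, tolerance = 1e-9)

  # inverse consistency: the returned n meets the target, n - 1 does not
  for (p1 in c(0.54, 0.58, 0.35)) {
    n <- sample_size_one_proportion(0.5, p1)
    expect_gte(power_one_proportion(0.5, p1, n), 0.8 - 1e-6)
    expect_lt(power_one_proportion(0.5, p1, n - 1), 0.8)
  }

  # power strictly increasing in n and in the effect size
  expect_gt(power_one_proportion(0.5, 0.54, 2000),
            power_one_proportion(0.5, 0.54, 1000))
  expect_gt(power_one_proportion(0.5, 0.58, 1000),
            power_one_proportion(0.5, 0.54, 1000))
})

test_that("Cronbach's alpha measures rater consistency", {
  # identical non-constant columns: alpha = 1
  col <- c(1, 0, 1, 1, 0, 1)
  expect_equal(cronbach_alpha(cbind(col, col, col, col)), 1)

  # toy matrix with one disagreement against the direct formula
  m <- cbind(r1 = c(1, 0, 1, 1, 0, 1), r2 = c(1, 0, 1, 0, 0, 1))
  k <- 2
  direct <- (k / (k - 1)) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  expect_equal(cronbach_alpha(m), direct)

  # independent random raters: alpha near 0
  set.seed(77)
  alphas <- vapply(1:100, function(i) {
    cronbach_alpha(matrix(rbinom(200, 1, 0.5), ncol = 4))
  }, numeric(1))
  expect_lt(abs(mean(alphas)), 0.1)
  expect_true(all(alphas <= 1))  # negative excursions below -1 are possible

  expect_error(cronbach_alpha(cbind(c(1, 1), c(1, 1))), "zero total-score variance")
  expect_error(cronbach_alpha(matrix(1:4, ncol = 1)), "at least 2 raters")
})
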