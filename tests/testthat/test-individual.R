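test_that("laterality index follows the signed-percentage formula", {
  expect_equal(laterality_index(8, 20), 42.857143, tolerance = 1e-6)
  expect_equal(laterality_index(7, 0), -100)
  expect_equal(laterality_index(10, 10), 0)
  expect_error(laterality_index(0, 0), "no observations")

  # antisymmetry under swapping the counts
  set.seed(7)
  for (i in 1:25) {
    a <- sample(0:40, 1); b <- sample(0:40, 1)
    if (a + b == 0) next
    expect_equal(laterality_index(a, b), -laterality_index(b, a))
  }
})

test_that("normal-approximation one-proportion test matches its closed form", {
  a <- one_proportion_test(20, 28)
  expect_equal(round(a$z, 2), 2.27)
  expect_equal(round(a$p_value, 3), 0.023)

  pooled <- one_proportion_test(1021, 2095)
  expect_equal(round(pooled$z, 2), -1.16)
  expect_equal(round(pooled$p_value, 2), 0.25)

  sym <- one_proportion_test(5, 10)
  expect_equal(sym$z, 0)
  expect_equal(sym$p_value, 1)

  # p = 2*Phi(-|z|) by construction; z antisymmetric under count -> n - count
  for (count in c(3, 8, 14)) {
    r1 <- one_proportion_test(count, 20)
    r2 <- one_proportion_test(20 - count, 20)
    expect_equal(r1$p_value, 2 * pnorm(-abs(r1$z)))
    expect_equal(r1$z, -r2$z)
  }
  expect_error(one_proportion_test(1, 0), "at least 1")
  expect_error(one_proportion_test(2, 10, p0 = 1), "between 0 and 1")
})

test_that("exact one-proportion test agrees with tail enumeration for all n <= 30", {
  for (n in 1:30) {
    for (count in 0:n) {
      got <- one_proportion_test(count, n, method = "exact")$p_value
      expect_equal(got, oracle_exact_two_sided(count, n), tolerance = 1e-12)
    }
  }
  # published low-count examples
  expect_equal(round(one_proportion_test(14, 18, method = "exact")$p_value, 3), 0.031)
  expect_equal(one_proportion_test(0, 6, method = "exact")$p_value, 0.03125)
  expect_equal(one_proportion_test(8, 10, method = "exact")$p_value, 0.109375)
  # z is still reported from the normal formula alongside the exact p
  u <- one_proportion_test(0, 6, method = "exact")
  expect_equal(round(u$z, 2), -2.45)
})

test_that("per-horse assessment classifies and selects methods as specified", {
  res <- assess_laterality(focal_horses())

  b <- res[res$horse_id == "B", ]
  expect_equal(b$method, "exact")
  expect_equal(b$classification, "sig_R")

  n <- res[res$horse_id == "N", ]
  expect_equal(n$classification, "ambi")
  expect_equal(n$p_value, 1)

  l <- res[res$horse_id == "L", ]
  expect_equal(l$method, "normal")  # 31 observations exceeds the cutoff
  expect_equal(round(l$p_value, 3), 0.048)
  expect_equal(l$classification, "sig_L")

  # every row equals the scalar one_proportion_test at the same settings
  for (i in seq_len(nrow(res))) {
    ref <- one_proportion_test(res$n_right[i], res$n[i], method = res$method[i])
    expect_equal(res$z[i], ref$z)
    expect_equal(res$p_value[i], ref$p_value)
  }
})

test_that("per-side medians match the published footer values", {
  res <- assess_laterality(focal_horses())
  expect_equal(median_li(res, "L"), -60.00)
  expect_equal(round(median_li(res, "R"), 2), 42.86)
  one <- tibble::tibble(li = -10)
  expect_equal(median_li(one, "L"), -10)
  expect_error(median_li(one, "R"), "no individuals")
})
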