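make_starts <- function(n_l, n_r, direction = "C", winner_first = TRUE) {
  n <- n_l + n_r
  tibble::tibble(
    race_id = paste0("r", seq_len(n)),
    direction = direction,
    horse_id = paste0("h", seq_len(n)),
    lead = rep(c("L", "R"), c(n_l, n_r)),
    stall_position = 1L, age = 4L, sex = "mare",
    finish_position = if (winner_first) rep(1L, n) else rep(2L, n),
    is_winner = winner_first
  )
}

test_that("population proportion test reproduces the published course-level values", {
  cc <- population_proportion_test(make_starts(604, 527))
  expect_equal(round(cc$z, 2), -2.29)

  pooled <- population_proportion_test(make_starts(1074, 1021))
  expect_equal(round(pooled$z, 2), -1.16)
  expect_lt(abs(pooled$ci_low - 0.4659), 1e-4)
  expect_lt(abs(pooled$ci_high - 0.5087), 1e-4)

  acw <- population_proportion_test(make_starts(78, 69, direction = "AC"))
  expect_equal(round(acw$z, 2), -0.74)
  expect_equal(round(acw$p_value, 2), 0.46)

  # filters pass through to the counted subset
  mixed <- dplyr::bind_rows(make_starts(10, 30, "C"), make_starts(30, 10, "AC"))
  mixed$horse_id <- paste0("h", seq_len(nrow(mixed)))
  sub <- population_proportion_test(mixed, direction == "AC")
  expect_equal(sub$count, 10L)
  expect_equal(sub$n, 40L)
  expect_error(population_proportion_test(mixed, direction == "Z"), "no observations")
})

test_that("lead ratio divides counts and inverts cleanly", {
  expect_equal(round(lead_ratio(604, 527), 2), 1.15)
  expect_equal(lead_ratio(100, 100), 1)
  expect_equal(round(lead_ratio(78, 69), 2), 1.13)
  expect_equal(lead_ratio(3, 7) * lead_ratio(7, 3), 1)
  expect_error(lead_ratio(5, 0), "zero denominator")
})

test_that("lead association reports the likelihood-ratio G statistic", {
  # 2x2 tables against the direct G oracle
  for (tab in list(rbind(c(30, 10), c(10, 30)), rbind(c(20, 25), c(15, 40)))) {
    starts <- tibble::tibble(
      lead = rep(rep(c("R", "L"), 2), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])),
      grp = rep(c("a", "b"), c(sum(tab[1, ]), sum(tab[2, ])))
    )
    fit <- lead_association(starts, "grp")
    expect_equal(fit$chi_square, oracle_g_statistic(tab), tolerance = 1e-6)
    expect_equal(fit$df, 1)
  }

  # perfectly balanced response within each level: no association
  bal <- tibble::tibble(lead = rep(c("R", "L", "R", "L"), 25),
                        grp = rep(c("a", "a", "b", "b"), 25))
  fit0 <- lead_association(bal, "grp")
  expect_equal(fit0$chi_square, 0, tolerance = 1e-10)
  expect_equal(unname(coef(fit0$fit)["grpb"]), 0, tolerance = 1e-8)

  # chi-square invariant under L/R response recoding
  set.seed(31)
  starts <- tibble::tibble(
    lead = sample(c("L", "R"), 120, replace = TRUE, prob = c(0.4, 0.6)),
    grp = sample(c("a", "b", "c"), 120, replace = TRUE)
  )
  flipped <- dplyr::mutate(starts, lead = ifelse(lead == "L", "R", "L"))
  f1 <- lead_association(starts, "grp")
  f2 <- lead_association(flipped, "grp")
  expect_equal(f1$chi_square, f2$chi_square, tolerance = 1e-8)
  expect_equal(tidy(f1)$estimate[-1], -tidy(f2)$estimate[-1], tolerance = 1e-6)
  expect_equal(f1$df, 2)

  # complete separation is reported, not silently fitted
  sep <- tibble::tibble(lead = rep(c("R", "L"), c(20, 20)),
                        grp = rep(c("a", "b"), c(20, 20)))
  expect_error(suppressWarnings(lead_association(sep, "grp")), "separation")

  # sparse levels are dropped with a warning
  sparse <- dplyr::bind_rows(bal, tibble::tibble(lead = "R", grp = "z"))
  expect_warning(lead_association(sparse, "grp"), "fewer than 2")
})

test_that("one-way F test of LI on groups matches the pooled-t identity", {
  # identical group means give F = 0
  d0 <- tibble::tibble(li = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  expect_equal(li_anova(d0, li, g)$f_statistic, 0, tolerance = 1e-12)

  # two groups: F equals the square of the pooled-variance t
  set.seed(5)
  d <- tibble::tibble(li = c(rnorm(12, 0, 20), rnorm(9, 15, 20)),
                      g = rep(c("a", "b"), c(12, 9)))
  a <- li_anova(d, li, g)
  t_pooled <- two_sample_t(d$li[d$g == "a"], d$li[d$g == "b"], method = "pooled")
  expect_equal(a$f_statistic, t_pooled$t^2, tolerance = 1e-10)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 19)

  # fixture male/female split: df bookkeeping over 44 animals
  res <- assess_laterality(focal_horses())
  res$grp <- ifelse(res$sex == "mare", "female", "male")
  af <- li_anova(res, li, grp)
  expect_equal(af$df_between, 1)
  expect_equal(af$df_within, 42)

  expect_error(li_anova(tibble::tibble(li = 1:3, g = c("a", "a", "b")), li, g),
               "at least 2 values")
})
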