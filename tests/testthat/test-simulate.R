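test_that("simulation config validates its inputs", {
  expect_error(simulation_config(pi_left = 0.5, pi_right = 0.6, pi_ambi = 0),
               "sum to 1")
  expect_error(simulation_config(starts_min = 10, starts_max = 5), "starts_min")
  expect_error(simulation_config(horses_per_race = 16), "stall range")
  expect_s3_class(simulation_config(), "simulation_config")
})

test_that("configuration files round-trip through the YAML reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_horses: 10", "seed: 99", "starts_min: 8", "starts_max: 12",
               "sex_probs:", "  mare: 0.5", "  gelding: 0.3", "  stallion: 0.2"),
             path)
  cfg <- read_simulation_config(path)
  expect_equal(cfg$n_horses, 10)
  expect_equal(cfg$seed, 99L)
  expect_identical(simulate_focal_horses(cfg),
                   simulate_focal_horses(simulation_config(
                     n_horses = 10, seed = 99, starts_min = 8, starts_max = 12,
                     sex_probs = c(mare = 0.5, gelding = 0.3, stallion = 0.2))))
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_key: 1", bad)
  expect_error(read_simulation_config(bad), "unknown configuration key")
})

test_that("focal simulation is deterministic and respects the latent classes", {
  cfg <- simulation_config(n_horses = 60, seed = 123)
  a <- simulate_focal_horses(cfg)
  b <- simulate_focal_horses(cfg)
  expect_identical(a, b)

  expect_true(all(a$theta[a$true_class == "AMBI"] == 0.5))
  expect_true(all(a$theta[a$true_class == "R"] > 0.5))
  expect_true(all(a$theta[a$true_class == "L"] < 0.5))
  expect_true(all(nchar(a$sequence) == a$n_starts))
  expect_true(all(a$n_starts >= 5 & a$n_starts <= 46))

  # per-animal substreams: enlarging the cohort keeps earlier animals
  big <- simulate_focal_horses(simulation_config(n_horses = 80, seed = 123))
  expect_identical(big[1:60, ], a)

  # degenerate fully-lateralised right-biased cohort
  deg <- simulate_focal_horses(simulation_config(
    n_horses = 20, pi_left = 0, pi_right = 1, pi_ambi = 0,
    bias_shape_b = 0, seed = 5))
  expect_true(all(grepl("^R+$", deg$sequence)))
  expect_true(all(assess_laterality(deg)$li == 100))
})

test_that("an all-ambilateral cohort is rarely called significant", {
  cfg <- simulation_config(n_horses = 200, pi_left = 0, pi_right = 0,
                           pi_ambi = 1, starts_min = 40, starts_max = 40,
                           seed = 42)
  res <- assess_laterality(simulate_focal_horses(cfg))
  expect_lte(mean(res$classification %in% c("sig_L", "sig_R")), 0.07)
})

test_that("race cohorts have the stated layout and near-balanced leads", {
  cfg <- simulation_config(n_races = 500, horses_per_race = 10, seed = 9)
  starts <- simulate_race_cohort(cfg)
  expect_equal(nrow(starts), 5000)
  expect_equal(dplyr::n_distinct(starts$horse_id), 5000)  # dedup-safe ids
  expect_identical(deduplicate_horses(starts), starts)
  winners <- dplyr::count(starts, race_id, wt = is_winner)
  expect_true(all(winners$n == 1))
  expect_true(all(starts$stall_position %in% 1:10))
  expect_setequal(unique(starts$direction), c("C", "AC"))

  # balanced mixture, no direction effect: pooled R proportion within
  # 3 binomial standard errors of one half
  p_hat <- mean(starts$lead == "R")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 5000))

  one_race <- simulate_race_cohort(simulation_config(n_races = 1,
                                                     horses_per_race = 15,
                                                     seed = 3))
  expect_equal(sum(one_race$is_winner), 1)
})

test_that("a strong clockwise-course effect is detected at the designed power", {
  # ambilateral animals with a -1 log-odds shift on C courses: the
  # C-course left excess should be picked up by the population test
  cfg <- simulation_config(n_races = 300, horses_per_race = 10,
                           pi_left = 0, pi_right = 0, pi_ambi = 1,
                           direction_effect = -1, seed = 20)
  starts <- simulate_race_cohort(cfg)
  cc <- population_proportion_test(starts, direction == "C")
  expect_lt(cc$z, 0)
  expect_lt(cc$p_value, 0.001)
  # AC courses stay balanced
  acc <- population_proportion_test(starts, direction == "AC")
  expect_gt(acc$p_value, 0.01)
})

test_that("classification operating characteristics match binomial expectations", {
  # near-fully lateralised animals with 40 starts are essentially always found
  strong <- simulation_config(n_horses = 50, pi_left = 0, pi_right = 1,
                              pi_ambi = 0, bias_shape_a = 900,
                              bias_shape_b = 100, starts_min = 40,
                              starts_max = 40, seed = 7)
  rs <- recovery_study(strong, replicates = 20)
  expect_gte(rs$sensitivity, 0.99)
  expect_equal(rs$sign_accuracy, 1)

  # five starts can never reach two-sided exact significance (floor 2 * 0.5^5)
  few <- simulation_config(n_horses = 50, pi_left = 0, pi_right = 1,
                           pi_ambi = 0, bias_shape_b = 0,
                           starts_min = 5, starts_max = 5, seed = 8)
  rs5 <- recovery_study(few, replicates = 5)
  expect_equal(rs5$sensitivity, 0)
})

test_that("mean simulated LI converges to the bias-law mean for long records", {
  cfg <- simulation_config(n_horses = 400, pi_left = 0, pi_right = 1,
                           pi_ambi = 0, bias_shape_a = 2, bias_shape_b = 3,
                           starts_min = 10000, starts_max = 10000, seed = 15)
  sim <- simulate_focal_horses(cfg)
  res <- assess_laterality(sim)
  # per-horse LI converges to 100 * (2 theta - 1) ...
  expect_lt(abs(mean(res$li) - mean(100 * (2 * sim$theta - 1))), 0.5)
  # ... whose mixture mean is 100 * E[B] = 100 * a/(a+b) = 40
  expect_lt(abs(mean(res$li) - 40), 2)
})
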