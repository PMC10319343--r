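# Synthetic-data generators: seed reproducibility, forced structure, and
# parameter recovery against closed-form expectations.

test_that("every generator is reproducible seed for seed", {
  cfg <- proteome_sim_config(30, c("A", "B"), sporadic_missing_rate = 0.1,
                             seed = 11)
  expect_identical(simulate_intensity_table(cfg), simulate_intensity_table(cfg))

  gcfg <- germination_sim_config(daily_germination_probs = c(0.3, 0.5, 0.4),
                                 seed = 12)
  expect_identical(simulate_germination_counts(gcfg),
                   simulate_germination_counts(gcfg))

  expect_identical(simulate_qpcr_curve(1.9, 1e-5, noise_sd = 0.01, seed = 13),
                   simulate_qpcr_curve(1.9, 1e-5, noise_sd = 0.01, seed = 13))
  expect_identical(simulate_comet_counts(rep(0.2, 5), seed = 14),
                   simulate_comet_counts(rep(0.2, 5), seed = 14))

  # different seeds give different draws
  cfg2 <- proteome_sim_config(30, c("A", "B"), seed = 99)
  expect_false(identical(simulate_intensity_table(cfg)$intensities,
                         simulate_intensity_table(cfg2)$intensities))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(42)
  before <- .Random.seed
  invisible(simulate_intensity_table(proteome_sim_config(5, c("A", "B"))))
  invisible(simulate_comet_counts(rep(0.2, 5), seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("absent pairs force complete condition-wise missingness", {
  cfg <- proteome_sim_config(
    20, c("A", "B"), seed = 5,
    absent_pairs = data.frame(protein = "P0001", condition = "B"))
  tab <- simulate_intensity_table(cfg)
  b_cols <- tab$condition_of == "B"
  expect_true(all(tab$intensities["P0001", b_cols] == 0))
  expect_true(all(tab$intensities["P0001", !b_cols] > 0))
})

test_that("invalid simulation configs are rejected with messages", {
  expect_error(proteome_sim_config(10, c("A", "B"),
                                   n_replicates_per_condition = 1),
               ">= 2")
  expect_error(proteome_sim_config(10, c("A", "B"), replicate_sd = 0),
               "replicate_sd")
  expect_error(proteome_sim_config(10, c("A", "B"),
                                   sporadic_missing_rate = 1.2),
               "\\[0, 1\\]")
  expect_error(germination_sim_config(daily_germination_probs = c(0.5, 1.3)),
               "probabilities")
  expect_error(germination_sim_config(daily_germination_probs = c(0.5, 0.5),
                                      time_points = c(2, 1)),
               "increasing")
  expect_error(simulate_qpcr_curve(E_true = 1, F0 = 1e-5), "E_true")
  expect_error(simulate_comet_counts(c(0.5, 0.5, 0.2, 0, 0)), "sum to 1")
})

test_that("germination hazards at the extremes behave deterministically", {
  all_day1 <- simulate_germination_counts(
    germination_sim_config(daily_germination_probs = c(1, 0.5),
                           time_points = c(1, 2), seed = 2))
  expect_true(all(all_day1$new_germinations[all_day1$time_days == 1] == 20))
  expect_true(all(all_day1$new_germinations[all_day1$time_days == 2] == 0))

  none <- simulate_germination_counts(
    germination_sim_config(daily_germination_probs = c(0, 0, 0), seed = 2))
  expect_true(all(none$new_germinations == 0))

  many <- simulate_germination_counts(
    germination_sim_config(n_replicates = 500,
                           daily_germination_probs = c(0.4, 0.6), seed = 3))
  totals <- tapply(many$new_germinations, many$replicate, sum)
  expect_true(all(totals <= 20))
})

test_that("simulated germinability matches its closed-form expectation", {
  # constant hazard 0.5 over three intervals: P(germinate) = 1 - 0.5^3
  cfg <- germination_sim_config(n_replicates = 2000, n_seeds = 20,
                                daily_germination_probs = c(0.5, 0.5, 0.5),
                                seed = 21)
  counts <- simulate_germination_counts(cfg)
  g <- 100 * tapply(counts$new_germinations, counts$replicate, sum) / 20
  expected <- 100 * (1 - 0.5^3)
  se <- stats::sd(g) / sqrt(length(g))
  expect_lt(abs(mean(g) - expected), 3 * se + 1e-9)
})

test_that("noiseless qPCR curves amplify exactly by E per cycle", {
  curve <- simulate_qpcr_curve(E_true = 1.87, F0 = 1e-6, noise_sd = 0,
                               plateau = 5, seed = 1)
  below <- which(curve$fluorescence < 5 * 0.999)
  below <- below[-length(below)]
  ratios <- curve$fluorescence[below + 1] / curve$fluorescence[below]
  expect_equal(ratios, rep(1.87, length(ratios)), tolerance = 1e-12)
  # saturation: non-decreasing, bounded by the plateau
  expect_true(all(diff(curve$fluorescence) >= -1e-12))
  expect_true(all(curve$fluorescence <= 5 + 1e-12))
})

test_that("comet count draws respect the multinomial structure", {
  pure0 <- simulate_comet_counts(c(1, 0, 0, 0, 0), n_nucleoids = 77, seed = 4)
  expect_identical(unname(pure0), c(77L, 0L, 0L, 0L, 0L))
  for (s in 1:20) {
    draw <- simulate_comet_counts(c(0.2, 0.3, 0.25, 0.15, 0.1),
                                  n_nucleoids = 100, seed = s)
    expect_identical(sum(draw), 100L)
  }
  pure4 <- simulate_comet_counts(c(0, 0, 0, 0, 1), n_nucleoids = 100, seed = 6)
  expect_equal(comet_score(pure4), 400)
})
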