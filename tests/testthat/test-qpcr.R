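# qPCR: window-of-linearity efficiency/Ct recovery, Pfaffl arithmetic,
# reference combination, and the full curve-to-fold-change chain.

test_that("efficiency and Ct are recovered exactly from noiseless curves", {
  for (E in c(2, 1.9)) {
    curve <- simulate_qpcr_curve(E_true = E, F0 = 1e-3, noise_sd = 0,
                                 plateau = 3, seed = 1)
    fit <- estimate_efficiency_ct(curve$cycle, curve$fluorescence)
    expect_equal(fit$E, E, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
    expect_false(fit$low_quality)
    # Ct: the fitted exponential crosses 20% of the curve maximum there
    expect_equal(1e-3 * E^fit$Ct, 0.2 * max(curve$fluorescence),
                 tolerance = 1e-6)
    expect_gte(fit$Ct, min(curve$cycle))
    expect_lte(fit$Ct, max(curve$cycle))
  }
})

test_that("efficiency recovery degrades gracefully with plateau-scale noise", {
  rel_err <- function(noise_sd, seeds) {
    vapply(seeds, function(s) {
      curve <- simulate_qpcr_curve(E_true = 1.95, F0 = 1e-6, n_cycles = 45,
                                   noise_sd = noise_sd, plateau = 3, seed = s)
      fit <- estimate_efficiency_ct(curve$cycle, curve$fluorescence)
      abs(fit$E - 1.95) / 1.95
    }, numeric(1))
  }
  # low noise (0.2% of the plateau): within 2%
  expect_lt(max(rel_err(0.006, 1:10)), 0.02)
  # 1% of the plateau: within 5%
  expect_lt(max(rel_err(0.03, 1:10)), 0.05)
})

test_that("degenerate curves are rejected", {
  expect_error(estimate_efficiency_ct(1:10, rep(1, 10)), "flat curve")
  expect_error(estimate_efficiency_ct(1:10, 10:1 / 10), "flat|window")
  expect_error(estimate_efficiency_ct(1:3, c(1, 2, 4)), "cycles")
})

test_that("the Pfaffl ratio follows the efficiency-corrected formula", {
  expect_equal(pfaffl_ratio(2, 3, 2, 1), 4)
  expect_equal(pfaffl_ratio(2, 0, 2, 0), 1)
  expect_equal(pfaffl_ratio(1.9, 2, 2.0, 1), 1.9^2 / 2, tolerance = 1e-12)
  expect_error(pfaffl_ratio(1, 2, 2, 1), "> 1")
})

test_that("with both efficiencies 2 the Pfaffl ratio equals 2^-ddCt", {
  set.seed(8)
  for (i in 1:20) {
    d_t <- runif(1, -4, 4)
    d_r <- runif(1, -2, 2)
    # ddCt = dCt_ref - dCt_target under the control-minus-sample convention
    expect_equal(pfaffl_ratio(2, d_t, 2, d_r), 2^-(d_r - d_t),
                 tolerance = 1e-12)
  }
})

test_that("reference ratios combine by geometric mean", {
  expect_equal(combine_references(c(4, 1)), 2)
  expect_equal(combine_references(5), 5)
  expect_equal(combine_references(c(2, 8, 1)), combine_references(c(8, 1, 2)))
  expect_error(combine_references(c(2, -1)), "positive")
})

# simulate a two-condition experiment: target induced `fold`-fold in the
# second condition, references constant
simulate_experiment <- function(fold, E = 2, noise_sd = 0, n_rep = 3,
                                seed = 100) {
  curves <- list()
  k <- 0
  for (gene in c("TGT", "REF1", "REF2")) {
    for (cond in c("ctrl", "trt")) {
      f0 <- 1e-6 * if (gene == "TGT" && cond == "trt") fold else 1
      for (r in seq_len(n_rep)) {
        k <- k + 1
        curve <- simulate_qpcr_curve(E_true = E, F0 = f0, noise_sd = noise_sd,
                                     plateau = 3, seed = seed + k)
        curves[[k]] <- data.frame(reaction = paste0("rx", k), gene = gene,
                                  sample = paste0(cond, "_r", r),
                                  condition = cond, curve)
      }
    }
  }
  do.call(rbind, curves)
}

test_that("the curve-to-Pfaffl chain recovers programmed fold changes", {
  fits <- fit_qpcr_reactions(simulate_experiment(fold = 4, noise_sd = 0.005))
  rel <- relative_expression(fits, targets = "TGT",
                             references = c("REF1", "REF2"),
                             transitions = list(c("ctrl", "trt")))
  expect_equal(rel$log2_fc, 2, tolerance = abs(log2(1.15)))
  expect_equal(rel$ratio, 4, tolerance = 0.15 * 4)

  # reversing the transition negates the log2 fold change exactly
  rev <- relative_expression(fits, targets = "TGT",
                             references = c("REF1", "REF2"),
                             transitions = list(c("trt", "ctrl")))
  expect_equal(rev$log2_fc, -rel$log2_fc, tolerance = 1e-9)

  # identical conditions give log2 FC 0
  same <- relative_expression(fits, targets = "REF1", references = "REF2",
                              transitions = list(c("ctrl", "trt")))
  expect_lt(abs(same$log2_fc), 0.2)

  # a missing condition is reported absent rather than failing
  missing_cond <- relative_expression(fits, targets = "TGT",
                                      references = "REF1",
                                      transitions = list(c("ctrl", "nope")))
  expect_true(is.na(missing_cond$log2_fc))
})
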