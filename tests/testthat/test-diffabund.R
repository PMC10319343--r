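# Differential abundance: filtering rules, normalization arithmetic,
# pooled-variance t, pseudo fold changes, BH adjustment and the full
# comparison chain.

# table with explicit intensities: one condition block per matrix
make_table <- function(first_block, second_block, peptides = NULL,
                       first = "A", second = "B") {
  n <- nrow(first_block)
  x <- cbind(first_block, second_block)
  rownames(x) <- sprintf("P%d", seq_len(n))
  colnames(x) <- c(paste0(first, "_r", seq_len(ncol(first_block))),
                   paste0(second, "_r", seq_len(ncol(second_block))))
  if (is.null(peptides)) peptides <- rep(3L, n)
  cond <- c(rep(first, ncol(first_block)), rep(second, ncol(second_block)))
  intensity_table(x, peptides, cond)
}

test_that("peptide and missing-value filters apply their boundaries", {
  a <- matrix(1000, 4, 5)
  b <- matrix(2000, 4, 5)
  # P1: one peptide; P2: exactly 4 missing spread over both conditions;
  # P3: 5 missing spread over both conditions; P4: clean
  a[2, 1:2] <- 0; b[2, 1:2] <- 0
  a[3, 1:3] <- 0; b[3, 1:2] <- 0
  tab <- make_table(a, b, peptides = c(1L, 2L, 2L, 5L))

  kept <- rownames(filter_proteins(tab, "A", "B")$intensities)
  expect_identical(kept, c("P2", "P4"))

  kept5 <- rownames(filter_proteins(tab, "A", "B", max_missing = 5)$intensities)
  expect_identical(kept5, c("P2", "P3", "P4"))
})

test_that("condition-absent proteins with a complete other condition are retained", {
  a <- matrix(1000, 2, 5)
  b <- matrix(2000, 2, 5)
  b[1, ] <- 0          # P1 absent in B, complete in A
  a[2, ] <- 0; b[2, 3] <- 0  # P2 absent in A but B also has a hole
  tab <- make_table(a, b)
  kept <- rownames(filter_proteins(tab, "A", "B")$intensities)
  expect_identical(kept, "P1")
})

test_that("robust z-scores use the 1.4826-scaled MAD and grand rescaling", {
  # two identically distributed samples: log2 values 1..5 each
  x <- matrix(2^(1:5), 5, 2)
  rownames(x) <- paste0("P", 1:5)
  colnames(x) <- c("A_r1", "B_r1")
  tab <- intensity_table(x, rep(2L, 5), c("A", "B"))
  norm <- normalize_robust_z(tab)
  grand_center <- 3
  grand_scale <- 1.4826 * 1
  z <- (norm$values[, 1] - grand_center) / grand_scale
  expect_equal(unname(z),
               c(-1.349, -0.674, 0, 0.674, 1.349), tolerance = 1e-3)
})

test_that("normalization matches an independent reimplementation and is rank-preserving", {
  tab <- random_table(40, c("A", "B"), n_rep = 4, seed = 3, missing_rate = 0.1)
  norm <- normalize_robust_z(tab)

  L <- log2(tab$intensities)
  L[tab$intensities == 0] <- NA
  gc <- median(L, na.rm = TRUE)
  gs <- 1.4826 * median(abs(L - gc), na.rm = TRUE)
  expected <- apply(L, 2, function(v) {
    gc + gs * (v - median(v, na.rm = TRUE)) /
      (1.4826 * median(abs(v - median(v, na.rm = TRUE)), na.rm = TRUE))
  })
  expect_equal(norm$values, expected, tolerance = 1e-12)

  # per-sample median equals the grand median; ranks preserved
  meds <- apply(norm$values, 2, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(gc, ncol(L)), tolerance = 1e-12)
  for (j in seq_len(ncol(L))) {
    ok <- !is.na(L[, j])
    expect_identical(order(L[ok, j]), order(norm$values[ok, j]))
  }
  # missingness pattern unchanged
  expect_identical(is.na(norm$values), tab$intensities == 0)
})

test_that("pooled-variance t matches the closed form and the reference", {
  res <- pooled_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t_stat, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4L)

  same <- pooled_t_test(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  # oracle equivalence against the stock equal-variance t-test
  set.seed(101)
  for (i in 1:300) {
    a <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2))
    mine <- pooled_t_test(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }

  # insufficient data degrades to NA, never an error
  expect_true(is.na(pooled_t_test(1, c(1, 2))$p_value))
})

test_that("log2 fold changes follow the second-over-first convention", {
  tab <- make_table(matrix(2, 1, 3), matrix(8, 1, 3))
  fc <- log2_fold_change(tab, "P1", "A", "B")
  expect_equal(fc$log2_fc, 2)
  expect_false(fc$is_pseudo_fc)
  # antisymmetry under comparison reversal
  expect_equal(log2_fold_change(tab, "P1", "B", "A")$log2_fc, -2)
})

test_that("pseudo fold changes use the mean of the 10% smallest condition means", {
  # P1 absent in B; the other proteins set B's floor: 10% of 10 quantified
  # proteins -> the single smallest condition mean, which is 10
  a <- matrix(40, 11, 5)
  b <- matrix(rep(seq(10, 100, by = 10), each = 5), 10, 5, byrow = TRUE)
  b <- rbind(matrix(0, 1, 5), b)
  tab <- make_table(a, b)
  fc <- log2_fold_change(tab, "P1", "A", "B")
  expect_true(fc$is_pseudo_fc)
  expect_identical(fc$detected_in, "first")
  expect_equal(fc$log2_fc, log2(10 / 40), tolerance = 1e-12)

  # pseudo-FC magnitude grows with the abundance of the detected condition
  a2 <- a; a2[1, ] <- 400
  tab2 <- make_table(a2, b)
  fc2 <- log2_fold_change(tab2, "P1", "A", "B")
  expect_lt(fc2$log2_fc, fc$log2_fc)

  # both conditions missing: skipped with warning
  a3 <- a; a3[1, ] <- 0
  tab3 <- make_table(a3, b)
  expect_warning(fc3 <- log2_fold_change(tab3, "P1", "A", "B"), "both")
  expect_true(is.na(fc3$log2_fc))
})

test_that("BH adjustment is monotone, order-preserving and permutation-invariant", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  set.seed(7)
  p <- runif(50)
  adj <- adjust_bh(p)
  expect_true(all(adj >= p))
  perm <- sample(50)
  expect_equal(adjust_bh(p[perm]), adj[perm])
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance classes follow the threshold rules", {
  expect_identical(classify_significance(1.2, 0.04, FALSE), "accumulated")
  expect_identical(classify_significance(-1.2, 0.04, FALSE), "depleted")
  expect_identical(classify_significance(-0.5, 0.04, FALSE), "not_significant")
  expect_identical(classify_significance(1.2, 0.06, FALSE), "not_significant")
  expect_identical(classify_significance(3, NA, TRUE, "second"), "only_in_second")
  expect_identical(classify_significance(-3, NA, TRUE, "first"), "only_in_first")
  expect_identical(classify_significance(0.4, NA, TRUE, "second"),
                   "not_significant")
})

test_that("the full comparison chain recovers spiked and absent proteins", {
  eff <- matrix(0, 60, 2, dimnames = list(NULL, c("A", "B")))
  eff[1, "B"] <- 3  # strong spike
  eff[2, ] <- 2     # abundant protein, then forced absent in B
  cfg <- proteome_sim_config(60, c("A", "B"), log2_effect_sizes = eff,
                             replicate_sd = 0.3, seed = 77,
                             absent_pairs = data.frame(protein = "P0002",
                                                       condition = "B"))
  tab <- simulate_intensity_table(cfg)
  res <- run_comparison(tab, "A", "B")
  st <- res$stats
  expect_identical(st$sig_class[st$protein_id == "P0001"], "accumulated")
  expect_identical(st$sig_class[st$protein_id == "P0002"], "only_in_first")
  expect_identical(res$summary$only_in_first, 1L)
  expect_true(st$is_pseudo_fc[st$protein_id == "P0002"])
  # adjusted p never below raw p
  ok <- !is.na(st$p_value)
  expect_true(all(st$adj_p[ok] >= st$p_value[ok]))
})

test_that("a null table yields essentially no discoveries after BH", {
  tab <- random_table(400, c("A", "B"), seed = 31)
  res <- run_comparison(tab, "A", "B")
  n_sig <- res$summary$accumulated + res$summary$depleted
  expect_lte(n_sig, 2)
})
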