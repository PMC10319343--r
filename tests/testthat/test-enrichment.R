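# Preranked enrichment: running-sum statistic against brute-force and
# reference oracles, permutation NES/p behaviour, and the hypergeometric
# over-representation tail.

test_that("the enrichment score reproduces hand-computed runs", {
  s <- c(a = 3, b = 2, c = 1, d = -1, e = -2)
  expect_equal(enrichment_score(s, c("a", "b"))$es, 1)
  expect_equal(enrichment_score(s, names(s))$es, 1)  # no misses
  # a set at the bottom with negative scores has a negative ES
  expect_lt(enrichment_score(s, c("d", "e"))$es, 0)
  # absent members flag the result
  expect_true(is.na(enrichment_score(s, "zz")$es))
})

test_that("ES matches the brute-force running-sum oracle on all small instances", {
  set.seed(5)
  for (n in 2:8) {
    scores <- stats::setNames(round(rnorm(n), 3), letters[seq_len(n)])
    for (mask in seq_len(2^n - 1)) {
      members <- letters[seq_len(n)][bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      es <- enrichment_score(scores, members)$es
      run <- brute_force_run(scores, members)
      # the ES magnitude is the running-sum extremum; when the positive and
      # negative extrema tie in magnitude, either sign is a valid report
      expect_equal(abs(es), max(abs(run)), tolerance = 1e-12)
      expect_true(min(abs(es - max(run)), abs(es - min(run))) < 1e-12)
      expect_gte(es, -1)
      expect_lte(es, 1)
    }
  }
})

test_that("ES weighting and sign behave under score transforms", {
  set.seed(9)
  scores <- stats::setNames(rnorm(30), paste0("g", 1:30))
  members <- paste0("g", sample(30, 8))
  # weight 0: invariant under positive affine rescaling of scores
  es0 <- enrichment_score(scores, members, weight_exponent = 0)$es
  es0b <- enrichment_score(2.5 * scores + 0, members, weight_exponent = 0)$es
  expect_equal(es0, es0b, tolerance = 1e-12)
  # negating all scores flips the sign of the ES
  es1 <- enrichment_score(scores, members)$es
  es1n <- enrichment_score(-scores, members)$es
  expect_equal(es1n, -es1, tolerance = 1e-12)
})

test_that("ES agrees with the reference preranked implementation", {
  skip_if_not_installed("fgsea")
  set.seed(13)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    scores <- stats::setNames(rnorm(n), paste0("g", seq_len(n)))
    members <- paste0("g", sample(n, sample(3:8, 1)))
    sorted <- sort(scores, decreasing = TRUE)
    ref <- fgsea::calcGseaStat(unname(sorted),
                               which(names(sorted) %in% members),
                               gseaParam = 1)
    expect_equal(enrichment_score(scores, members)$es, ref,
                 tolerance = 1e-10)
  }
})

test_that("permutation NES is seed-reproducible with sign matching ES", {
  set.seed(17)
  scores <- stats::setNames(rnorm(80), paste0("g", 1:80))
  members <- paste0("g", 1:10)
  r1 <- permutation_nes(scores, members, n_perm = 200, seed = 4)
  r2 <- permutation_nes(scores, members, n_perm = 200, seed = 4)
  expect_identical(r1, r2)
  expect_identical(sign(r1$nes), sign(r1$es))
  expect_gte(r1$p_value, 1 / 201)
})

test_that("a top-loaded set in a spiked ranking is detected", {
  set.seed(19)
  scores <- stats::setNames(c(rnorm(10, mean = 4), rnorm(90)),
                            paste0("g", 1:100))
  res <- permutation_nes(scores, paste0("g", 1:10), n_perm = 999, seed = 23)
  expect_gt(res$nes, 0)
  expect_lte(res$p_value, 0.05)
})

test_that("gsea_preranked applies size bounds and BH across sets", {
  set.seed(29)
  scores <- stats::setNames(rnorm(50), paste0("g", 1:50))
  sets <- list(big = paste0("g", 1:20), tiny = paste0("g", 1:3),
               other = paste0("g", 21:35))
  res <- gsea_preranked(scores, sets, n_perm = 100, seed = 1, min_size = 5)
  expect_setequal(res$set, c("big", "other"))
  expect_true(all(res$adj_p >= res$p_value))
})

test_that("hypergeometric enrichment equals the exhaustive tail sum", {
  background <- paste0("g", 1:20)
  selected <- paste0("g", 1:10)
  sets <- list(S = paste0("g", c(1:5, 11:15)))  # K = 10, k = 5
  res <- hypergeometric_enrichment(selected, background, sets)
  expect_equal(res$p_value, brute_force_hyper_tail(5, 10, 20, 10),
               tolerance = 1e-12)
  expect_equal(res$fold_enrichment, (5 / 10) / (10 / 20), tolerance = 1e-12)
})

test_that("hypergeometric degenerate cases behave as bounds dictate", {
  sel <- paste0("g", 1:5)
  # set identical to selection and background: p = 1, fold = 1
  res <- hypergeometric_enrichment(sel, sel, list(S = sel))
  expect_equal(res$p_value, 1)
  expect_equal(res$fold_enrichment, 1)
  # empty intersection: fold 0, p = 1
  res2 <- hypergeometric_enrichment(sel, c(sel, "g9"), list(S = "g9"))
  expect_equal(res2$fold_enrichment, 0)
  expect_equal(res2$p_value, 1)
  # selection must be a subset of the background
  expect_error(hypergeometric_enrichment(c(sel, "zz"), sel, list(S = sel)),
               "subset")
})
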