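# Independent oracles used across tests. These deliberately re-derive the
# statistics from first principles (direct loops, enumeration, closed
# forms) so they share no code with the implementations they check.

# Running-sum enrichment by direct loop over the ranking; returns the
# whole running sum so callers can compare against either extremum (the
# positive maximum and negative minimum can tie in magnitude, in which
# case the reported ES is implementation-defined up to sign).
brute_force_run <- function(scores, members, weight_exponent = 1) {
  ord <- order(-scores)
  s <- unname(scores[ord])
  ids <- names(scores)[ord]
  n <- length(s)
  hits <- ids %in% members
  sum_w <- sum(abs(s[hits])^weight_exponent)
  run <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    if (hits[i]) {
      acc <- acc + (if (sum_w > 0) abs(s[i])^weight_exponent / sum_w
                    else 1 / sum(hits))
    } else {
      acc <- acc - 1 / (n - sum(hits))
    }
    run[i] <- acc
  }
  run
}

# Upper-tail hypergeometric probability by explicit summation.
brute_force_hyper_tail <- function(k, K, N, n) {
  total <- choose(N, n)
  sum(vapply(k:min(K, n), function(j) {
    choose(K, j) * choose(N - K, n - j) / total
  }, numeric(1)))
}

# Random intensity table with independent per-entry structure, for
# property tests.
random_table <- function(n_proteins, conditions, n_rep = 5, seed = 1,
                         missing_rate = 0, effects = NULL) {
  cfg <- proteome_sim_config(
    n_proteins = n_proteins, conditions = conditions,
    n_replicates_per_condition = n_rep,
    log2_effect_sizes = effects,
    sporadic_missing_rate = missing_rate, seed = seed)
  simulate_intensity_table(cfg)
}
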