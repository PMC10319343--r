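# Preranked gene-set enrichment on t-statistic rankings: weighted
# Kolmogorov-Smirnov running-sum enrichment score, sign-matched
# permutation normalization (NES) and permutation p-values, plus a
# hypergeometric over-representation analysis for discrete protein
# selections.

# Sort scores decreasingly with stable tie order; returns list(scores, ids).
ranked_order <- function(scores) {
  if (is.null(names(scores))) fail("`scores` must be named by item ID")
  if (anyDuplicated(names(scores))) fail("duplicate IDs in ranking")
  if (any(!is.finite(scores))) fail("scores must be finite")
  ord <- order(-scores)  # order() is stable: ties keep input order
  list(scores = unname(scores[ord]), ids = names(scores)[ord])
}

# ES from a sorted ranking and a logical hit vector.
es_from_hits <- function(sorted_scores, hit, weight_exponent) {
  n <- length(sorted_scores)
  nh <- sum(hit)
  w <- abs(sorted_scores[hit])^weight_exponent
  sw <- sum(w)
  inc <- if (sw > 0) w / sw else rep(1 / nh, nh)
  delta <- numeric(n)
  delta[hit] <- inc
  if (n > nh) delta[!hit] <- -1 / (n - nh)
  run <- cumsum(delta)
  es <- run[which.max(abs(run))]
  list(es = es, running_sum = run)
}

#' Enrichment score of a gene set in a ranked list
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic of preranked gene-set
#' enrichment: walking down the ranking (scores sorted decreasingly, ties
#' in stable input order), set members increment the running sum by
#' `|score|^weight / sum(|score|^weight over members)` and non-members
#' decrement it by `1/(N - n_hits)`; the enrichment score is the running
#' sum's extremum of largest magnitude, always in `[-1, 1]`.
#'
#' @param scores Named numeric vector (item ID -> ranking score, e.g. the
#'   comparison t-statistic); sorted internally.
#' @param members Character vector of set member IDs.
#' @param weight_exponent Score weighting exponent (default 1, the classic
#'   weighting; 0 gives the unweighted statistic).
#' @return List with `es`, `running_sum` (in ranking order), `n_members`
#'   (members present in the ranking). If no member is present, `es` is
#'   `NA`.
#' @export
#' @examples
#' s <- c(a = 3, b = 2, c = 1, d = -1, e = -2)
#' enrichment_score(s, c("a", "b"))$es  # 1
enrichment_score <- function(scores, members, weight_exponent = 1) {
  r <- ranked_order(scores)
  hit <- r$ids %in% members
  if (!any(hit))
    return(list(es = NA_real_, running_sum = NULL, n_members = 0L))
  out <- es_from_hits(r$scores, hit, weight_exponent)
  out$n_members <- sum(hit)
  out
}

#' Permutation-normalized enrichment score
#'
#' Builds a null distribution of enrichment scores from `n_perm` random
#' member sets of the same size drawn from the ranking, normalizes the
#' observed score by the mean magnitude of same-sign null scores
#' (`NES = ES / mean(|null ES| of matching sign)`), and reports the
#' one-tailed permutation p-value within the same-sign null:
#' `p = (1 + #same-sign null >= |ES|) / (1 + #same-sign null)`, so p is
#' never below `1/(n_perm + 1)` and is uniform for null sets.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; results are seed-reproducible.
#' @return List with `es`, `nes`, `p_value`, `n_members`. A degenerate null
#'   (no same-sign permutation score, or all zero) yields `nes = NA`,
#'   `p_value = 1`.
#' @export
permutation_nes <- function(scores, members, n_perm = 1000, seed = 1,
                            weight_exponent = 1) {
  if (!is_count(n_perm) || n_perm < 1) fail("`n_perm` must be >= 1")
  r <- ranked_order(scores)
  hit <- r$ids %in% members
  nh <- sum(hit)
  if (nh == 0)
    return(list(es = NA_real_, nes = NA_real_, p_value = NA_real_,
                n_members = 0L))
  es <- es_from_hits(r$scores, hit, weight_exponent)$es
  n <- length(r$scores)
  null_es <- with_preserved_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      h <- logical(n)
      h[sample.int(n, nh)] <- TRUE
      es_from_hits(r$scores, h, weight_exponent)$es
    }, numeric(1))
  })
  if (es == 0) {
    return(list(es = 0, nes = 0, p_value = 1, n_members = nh))
  }
  same <- null_es[sign(null_es) == sign(es)]
  if (!length(same) || mean(abs(same)) == 0)
    return(list(es = es, nes = NA_real_, p_value = 1, n_members = nh))
  nes <- es / mean(abs(same))
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(es = es, nes = nes, p_value = p, n_members = nh)
}

#' Preranked enrichment over a gene-set collection
#'
#' Applies [permutation_nes()] to every gene set within the configured size
#' bounds and BH-adjusts the permutation p-values. Per-set permutation
#' streams are derived deterministically from `seed` and the set's position,
#' so the full table is seed-reproducible.
#'
#' @inheritParams permutation_nes
#' @param gene_sets Named list of member-ID vectors (e.g. from
#'   [read_gmt()]).
#' @param min_size,max_size Bounds on the number of set members present in
#'   the ranking (defaults 5 and 500); sets outside the bounds are skipped.
#' @return A data.frame with one row per retained set: `set`, `n_members`,
#'   `es`, `nes`, `p_value`, `adj_p`.
#' @export
gsea_preranked <- function(scores, gene_sets, n_perm = 1000, seed = 1,
                           weight_exponent = 1, min_size = 5, max_size = 500) {
  ids <- names(scores)
  rows <- lapply(seq_along(gene_sets), function(i) {
    present <- sum(gene_sets[[i]] %in% ids)
    if (present < min_size || present > max_size) return(NULL)
    res <- permutation_nes(scores, gene_sets[[i]], n_perm = n_perm,
                           seed = seed + i, weight_exponent = weight_exponent)
    data.frame(set = names(gene_sets)[i], n_members = res$n_members,
               es = res$es, nes = res$nes, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("no gene set within the size bounds")
    return(data.frame(set = character(), n_members = integer(),
                      es = numeric(), nes = numeric(), p_value = numeric(),
                      adj_p = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$adj_p <- adjust_bh(out$p_value)
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of drawing
#' at least the observed number of set members when sampling the selected
#' items from the background without replacement, plus the fold enrichment
#' `(k/n) / (K/N)`. P-values are BH-adjusted across sets.
#'
#' @param selected_items Character vector of selected IDs (e.g.
#'   differentially accumulated proteins); must be a subset of the
#'   background.
#' @param background_items Character vector of all quantifiable IDs.
#' @param gene_sets Named list of member-ID vectors.
#' @return A data.frame per set: `set`, `n_selected_in_set` (k),
#'   `n_set_in_background` (K), `fold_enrichment`, `p_value`, `adj_p`.
#' @export
hypergeometric_enrichment <- function(selected_items, background_items,
                                      gene_sets) {
  selected_items <- unique(selected_items)
  background_items <- unique(background_items)
  if (!all(selected_items %in% background_items))
    fail("`selected_items` must be a subset of `background_items`")
  n <- length(selected_items)
  N <- length(background_items)
  rows <- lapply(names(gene_sets), function(nm) {
    set_bg <- intersect(gene_sets[[nm]], background_items)
    K <- length(set_bg)
    k <- length(intersect(set_bg, selected_items))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (k == 0 || n == 0 || K == 0) 0 else (k / n) / (K / N)
    data.frame(set = nm, n_selected_in_set = k, n_set_in_background = K,
               fold_enrichment = fold, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- adjust_bh(out$p_value)
  out
}
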