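# Cross-layer statistics: Pearson correlation of transcript vs protein
# log2 fold changes (with pairwise exclusion of absent cells) and the
# Mann-Whitney U procedure (exact enumeration for small samples, normal
# approximation with tie correction otherwise).

#' Pearson correlation with pairwise exclusion of absent values
#'
#' Sample Pearson r with a two-sided t-based p-value
#' (`t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom). Pairs in which
#' either value is missing are dropped and the exclusion count reported.
#'
#' @param x,y Numeric vectors of equal length (`NA` allowed).
#' @return List with `r`, `p_value`, `n` (pairs used), `n_dropped`. With
#'   fewer than 3 complete pairs or zero variance in either vector, `r` is
#'   `NA` and a `message` field explains why.
#' @export
#' @examples
#' pearson_correlation(1:10, 2 * (1:10) + 1)$r  # 1
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) fail("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  out <- list(r = NA_real_, p_value = NA_real_, n = n, n_dropped = n_dropped)
  if (n < 3) {
    out$message <- "fewer than 3 complete pairs"
    return(out)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    out$message <- "zero variance in one of the vectors"
    return(out)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    out$r <- r; out$p_value <- 0
    return(out)
  }
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  out$r <- r
  out$p_value <- 2 * stats::pt(-abs(t_stat), n - 2)
  out
}

# U statistic (group a relative to b), counting 0.5 for ties.
u_statistic <- function(a, b) {
  sum(vapply(a, function(v) sum(v > b) + 0.5 * sum(v == b), numeric(1)))
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test of two independent groups. For small samples
#' (`max(n_a, n_b) <= 8`) the two-sided p-value is computed by exact
#' enumeration of all group assignments of the pooled values (ties handled
#' by enumeration, with `p = 2 min(P(U <= u), P(U >= u))` capped at 1);
#' larger samples use the normal approximation with tie correction.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `U` (statistic of group a), `p_value`, and `method`
#'   (`"exact"` or `"normal_approximation"`).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mann_whitney_u <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (!length(a) || !length(b)) fail("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  u <- u_statistic(a, b)

  if (max(na, nb) <= 8) {
    pooled <- c(a, b)
    combs <- utils::combn(na + nb, na)
    null_u <- apply(combs, 2, function(ix) {
      u_statistic(pooled[ix], pooled[-ix])
    })
    eps <- 1e-9
    p <- 2 * min(mean(null_u <= u + eps), mean(null_u >= u - eps))
    return(list(U = u, p_value = min(p, 1), method = "exact"))
  }

  n <- na + nb
  mu <- na * nb / 2
  ties <- table(c(a, b))
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_corr)
  if (sigma2 <= 0) return(list(U = u, p_value = 1,
                               method = "normal_approximation"))
  z <- (u - mu) / sqrt(sigma2)
  list(U = u, p_value = 2 * stats::pnorm(-abs(z)),
       method = "normal_approximation")
}

#' Correlate transcript and protein log2 fold changes across transitions
#'
#' Joins two long fold-change tables (columns `gene`/`protein`, `first`,
#' `second`, `log2_fc`) on entity and transition, drops pairs with an
#' absent value on either layer, and reports both the Pearson correlation
#' and the Mann-Whitney comparison of the two layers' fold-change
#' distributions.
#'
#' @param transcript_fc,protein_fc Data.frames with columns `gene`,
#'   `first`, `second`, `log2_fc`.
#' @return List with `pairs` (the joined data.frame), `pearson` (from
#'   [pearson_correlation()]) and `mann_whitney` (from
#'   [mann_whitney_u()]).
#' @export
correlate_layers <- function(transcript_fc, protein_fc) {
  need <- c("gene", "first", "second", "log2_fc")
  if (!all(need %in% names(transcript_fc)) || !all(need %in% names(protein_fc)))
    fail("both tables need columns: %s", paste(need, collapse = ", "))
  key <- function(d) paste(d$gene, d$first, d$second, sep = "|")
  m <- merge(
    data.frame(k = key(transcript_fc), transcript_log2_fc = transcript_fc$log2_fc,
               gene = transcript_fc$gene, first = transcript_fc$first,
               second = transcript_fc$second, stringsAsFactors = FALSE),
    data.frame(k = key(protein_fc), protein_log2_fc = protein_fc$log2_fc,
               stringsAsFactors = FALSE),
    by = "k")
  m$k <- NULL
  pearson <- pearson_correlation(m$transcript_log2_fc, m$protein_log2_fc)
  ok <- is.finite(m$transcript_log2_fc) & is.finite(m$protein_log2_fc)
  mw <- if (sum(ok) >= 1)
    mann_whitney_u(m$transcript_log2_fc[ok], m$protein_log2_fc[ok]) else NULL
  list(pairs = m, pearson = pearson, mann_whitney = mw)
}
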