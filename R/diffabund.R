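# Differential protein abundance for one pairwise comparison of
# conditions: peptide/missingness filtering, modified robust z-score
# normalization, pooled-variance t-tests, log2 fold changes with pseudo
# fold-change imputation for condition-absent proteins, BH adjustment and
# significance classing. Fold changes follow the "second condition over the
# first condition" convention throughout.

#' Filter proteins by peptide evidence and missingness
#'
#' Retains protein groups supported by at least `min_peptides` peptides
#' whose missing-value count across the two compared conditions' samples is
#' at most `max_missing`. A protein completely absent from one condition
#' but fully quantified in the other is always retained: these are the
#' "detected only in one condition" proteins that later receive a pseudo
#' fold change.
#'
#' @param table An [intensity_table()].
#' @param first,second Condition labels of the comparison (second over
#'   first).
#' @param min_peptides Minimum peptide count (default 2).
#' @param max_missing Maximum missing values across the comparison's
#'   samples (default 4).
#' @return The filtered [intensity_table()] restricted to the comparison's
#'   samples. Warns if no protein survives.
#' @export
filter_proteins <- function(table, first, second,
                            min_peptides = 2, max_missing = 4) {
  check_comparison(table, first, second)
  tab <- subset_conditions(table, c(first, second))
  x <- tab$intensities
  in_first <- tab$condition_of == first
  in_second <- tab$condition_of == second
  miss_first <- rowSums(x[, in_first, drop = FALSE] == 0)
  miss_second <- rowSums(x[, in_second, drop = FALSE] == 0)
  n_first <- sum(in_first)
  n_second <- sum(in_second)

  enough_peptides <- tab$peptide_counts >= min_peptides
  few_missing <- (miss_first + miss_second) <= max_missing
  condition_absent <- (miss_first == n_first & miss_second == 0) |
    (miss_second == n_second & miss_first == 0)
  keep <- enough_peptides & (few_missing | condition_absent)
  if (!any(keep)) warning("no proteins pass the filter")
  intensity_table(x[keep, , drop = FALSE],
                  tab$peptide_counts[keep],
                  tab$condition_of)
}

check_comparison <- function(table, first, second) {
  stopifnot(inherits(table, "intensity_table"))
  if (!is.character(first) || !is.character(second) ||
      length(first) != 1 || length(second) != 1 || first == second)
    fail("`first` and `second` must be distinct condition labels")
  absent <- setdiff(c(first, second), unique(table$condition_of))
  if (length(absent)) fail("conditions not in table: %s",
                           paste(absent, collapse = ", "))
  invisible(TRUE)
}

#' Modified robust z-score normalization
#'
#' Present intensities are log2-transformed and, per sample, standardized
#' robustly as `(x - median) / (1.4826 * MAD)`. The "modified" step rescales
#' every sample's z-scores by the grand median and grand robust scale of
#' the pooled log2 data, so normalized values stay on a common,
#' interpretable log2-intensity-like scale and every sample's median equals
#' the grand median. A sample with zero MAD falls back to an IQR-based
#' scale (`IQR / 1.349`); if that is also zero the sample is centered only,
#' with a warning. Missing entries stay missing (`NA`).
#'
#' @param table An [intensity_table()] of raw intensities.
#' @return An object of class `normalized_table`: list with `values`
#'   (protein x sample matrix of normalized log2 intensities, `NA` =
#'   missing), `condition_of` and `peptide_counts`.
#' @export
normalize_robust_z <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  x <- table$intensities
  L <- suppressWarnings(log2(x))
  L[x == 0] <- NA

  grand_center <- stats::median(L, na.rm = TRUE)
  grand_scale <- 1.4826 * stats::median(abs(L - grand_center), na.rm = TRUE)
  if (!is.finite(grand_scale) || grand_scale == 0)
    grand_scale <- max(stats::IQR(L, na.rm = TRUE) / 1.349, 1)

  z <- L
  for (j in seq_len(ncol(L))) {
    v <- L[, j]
    med <- stats::median(v, na.rm = TRUE)
    scale <- 1.4826 * stats::median(abs(v - med), na.rm = TRUE)
    if (!is.finite(scale) || scale == 0) {
      scale <- stats::IQR(v, na.rm = TRUE) / 1.349
      if (!is.finite(scale) || scale == 0) {
        warning(sprintf("sample %s has zero spread; centered only",
                        colnames(L)[j]))
        z[, j] <- v - med + grand_center
        next
      }
    }
    z[, j] <- grand_center + grand_scale * (v - med) / scale
  }
  structure(list(values = z,
                 condition_of = table$condition_of,
                 peptide_counts = table$peptide_counts),
            class = "normalized_table")
}

#' Two-sample t-test with pooled variance
#'
#' Classical equal-variance two-sample t: `df = n_a + n_b - 2`, pooled
#' variance `((n_a-1) s_a^2 + (n_b-1) s_b^2) / df`, two-sided p from the t
#' distribution. The statistic is `mean(a) - mean(b)` over its standard
#' error. With fewer than two present values in either group the result is
#' returned with `NA` fields rather than raising an error, so callers can
#' report the protein as unclassified.
#'
#' @param group_a,group_b Numeric vectors; `NA`s are dropped.
#' @return List with `t_stat`, `df`, `p_value`.
#' @export
#' @examples
#' pooled_t_test(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
pooled_t_test <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    return(list(t_stat = NA_real_, df = NA_integer_, p_value = NA_real_))
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  diff <- mean(a) - mean(b)
  if (sp2 == 0) {
    t_stat <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    t_stat <- diff / sqrt(sp2 * (1 / na + 1 / nb))
  }
  list(t_stat = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df))
}

# Per-protein condition means of raw intensities over quantified samples
# (NA when the protein has no quantified sample in the condition).
condition_means <- function(table, condition) {
  x <- table$intensities[, table$condition_of == condition, drop = FALSE]
  x[x == 0] <- NA
  rowMeans(x, na.rm = TRUE)
}

# log2 of the pseudo-count floor for a condition: the mean of the
# ceil(10%) smallest per-protein condition-mean intensities among proteins
# quantified in that condition.
pseudo_floor_log2 <- function(table, condition, pseudo_quantile = 0.1) {
  means <- condition_means(table, condition)
  means <- means[is.finite(means)]
  if (!length(means)) fail("no quantified proteins in condition %s", condition)
  k <- max(1L, ceiling(pseudo_quantile * length(means)))
  log2(mean(sort(means)[seq_len(k)]))
}

#' Log2 fold change of a protein, with pseudo fold-change imputation
#'
#' The fold change is `mean(log2 second) - mean(log2 first)` over the
#' quantified samples (second condition over the first). When a protein is
#' completely unquantified in one condition, that condition's group average
#' is replaced by the log2 of the mean of the 10% smallest per-protein
#' condition-mean intensities among proteins quantified in that condition
#' (at least one protein), and the result is flagged as a pseudo fold
#' change.
#'
#' @param table A filtered [intensity_table()] restricted to the two
#'   conditions.
#' @param protein_id Protein to evaluate.
#' @param first,second Condition labels (second over first).
#' @param pseudo_quantile Fraction of smallest condition means used for the
#'   pseudo floor (default 0.1).
#' @return List with `log2_fc`, `is_pseudo_fc`, `mean_log2_first`,
#'   `mean_log2_second`, and `detected_in` (`"first"`, `"second"`, or
#'   `"both"`). A protein missing in both conditions is reported with
#'   `NA` fold change and a warning.
#' @export
log2_fold_change <- function(table, protein_id, first, second,
                             pseudo_quantile = 0.1) {
  check_comparison(table, first, second)
  if (!protein_id %in% rownames(table$intensities))
    fail("unknown protein: %s", protein_id)
  v <- table$intensities[protein_id, ]
  mlog2 <- function(cond) {
    w <- v[table$condition_of == cond]
    w <- w[w > 0]
    if (length(w)) mean(log2(w)) else NA_real_
  }
  m1 <- mlog2(first)
  m2 <- mlog2(second)
  if (is.na(m1) && is.na(m2)) {
    warning(sprintf("protein %s unquantified in both conditions; skipped",
                    protein_id))
    return(list(log2_fc = NA_real_, is_pseudo_fc = FALSE,
                mean_log2_first = NA_real_, mean_log2_second = NA_real_,
                detected_in = NA_character_))
  }
  pseudo <- is.na(m1) || is.na(m2)
  detected_in <- if (!pseudo) "both" else if (is.na(m2)) "first" else "second"
  f1 <- if (is.na(m1)) pseudo_floor_log2(table, first, pseudo_quantile) else m1
  f2 <- if (is.na(m2)) pseudo_floor_log2(table, second, pseudo_quantile) else m2
  list(log2_fc = f2 - f1, is_pseudo_fc = pseudo,
       mean_log2_first = m1, mean_log2_second = m2,
       detected_in = detected_in)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with enforced monotonicity;
#' order-preserving with respect to the input, `NA`s passed through.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values in input order.
#' @export
adjust_bh <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    fail("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Assign a significance class
#'
#' Classes follow the comparison convention "second over first":
#' `accumulated` (more abundant in the second condition: adjusted p <
#' `alpha` and log2 FC >= `lfc_threshold`), `depleted` (more abundant in the
#' first: adjusted p < `alpha` and log2 FC <= -`lfc_threshold`),
#' `only_in_first` / `only_in_second` for pseudo fold changes whose
#' magnitude reaches the threshold, otherwise `not_significant`. A tested
#' protein without an adjusted p (insufficient data) is returned as `NA`
#' (unclassified).
#'
#' @param log2_fc Log2 fold change (second over first).
#' @param adj_p Adjusted p-value (ignored for pseudo fold changes).
#' @param is_pseudo_fc Whether the fold change is a pseudo fold change.
#' @param detected_in `"first"`, `"second"` or `"both"`.
#' @param alpha Significance level (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @return One of `"accumulated"`, `"depleted"`, `"only_in_first"`,
#'   `"only_in_second"`, `"not_significant"`, or `NA`.
#' @export
classify_significance <- function(log2_fc, adj_p, is_pseudo_fc,
                                  detected_in = "both",
                                  alpha = 0.05, lfc_threshold = 1) {
  if (isTRUE(is_pseudo_fc)) {
    if (is.na(log2_fc) || abs(log2_fc) < lfc_threshold) return("not_significant")
    return(if (detected_in == "second") "only_in_second" else "only_in_first")
  }
  if (is.na(log2_fc) || is.na(adj_p)) return(NA_character_)
  if (adj_p < alpha && log2_fc >= lfc_threshold) return("accumulated")
  if (adj_p < alpha && log2_fc <= -lfc_threshold) return("depleted")
  "not_significant"
}

#' Run one pairwise differential-abundance comparison
#'
#' The full chain: missingness/peptide filter, modified robust-z
#' normalization, per-protein pooled-variance t-test on normalized log2
#' values, log2 fold change on raw-intensity log2 means (pseudo fold change
#' for condition-absent proteins), BH adjustment, and significance
#' classing. The t statistic is oriented as second minus first so its sign
#' agrees with the fold change.
#'
#' @inheritParams filter_proteins
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @param pseudo_quantile Fraction of smallest condition means for the
#'   pseudo floor (default 0.1).
#' @return A list of class `comparison_result`: `stats` (one data.frame row
#'   per retained protein), `summary` (named counts: `total_quantified`,
#'   `accumulated`, `depleted`, `only_in_first`, `only_in_second`,
#'   `not_significant`, `unclassified`), and the comparison labels.
#' @export
run_comparison <- function(table, first, second,
                           min_peptides = 2, max_missing = 4,
                           alpha = 0.05, lfc_threshold = 1,
                           pseudo_quantile = 0.1) {
  filtered <- filter_proteins(table, first, second,
                              min_peptides = min_peptides,
                              max_missing = max_missing)
  norm <- normalize_robust_z(filtered)
  ids <- rownames(filtered$intensities)
  in_first <- filtered$condition_of == first
  in_second <- filtered$condition_of == second

  floors <- c(first = NA_real_, second = NA_real_)
  raw <- filtered$intensities
  n_first_present <- rowSums(raw[, in_first, drop = FALSE] > 0)
  n_second_present <- rowSums(raw[, in_second, drop = FALSE] > 0)
  if (any(n_first_present == 0))
    floors["first"] <- pseudo_floor_log2(filtered, first, pseudo_quantile)
  if (any(n_second_present == 0))
    floors["second"] <- pseudo_floor_log2(filtered, second, pseudo_quantile)

  rows <- lapply(ids, function(pid) {
    rv <- raw[pid, ]
    m1v <- rv[in_first]; m1v <- m1v[m1v > 0]
    m2v <- rv[in_second]; m2v <- m2v[m2v > 0]
    m1 <- if (length(m1v)) mean(log2(m1v)) else NA_real_
    m2 <- if (length(m2v)) mean(log2(m2v)) else NA_real_
    pseudo <- xor(is.na(m1), is.na(m2))
    detected_in <- if (!pseudo) "both" else if (is.na(m2)) "first" else "second"
    lfc <- (if (is.na(m2)) floors["second"] else m2) -
           (if (is.na(m1)) floors["first"] else m1)

    if (pseudo) {
      tt <- list(t_stat = NA_real_, df = NA_integer_, p_value = NA_real_)
    } else {
      nv <- norm$values[pid, ]
      tt <- pooled_t_test(nv[in_second], nv[in_first])
    }
    data.frame(protein_id = pid,
               n_present_first = unname(n_first_present[pid]),
               n_present_second = unname(n_second_present[pid]),
               mean_log2_first = m1, mean_log2_second = m2,
               log2_fc = unname(lfc), is_pseudo_fc = pseudo,
               t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value,
               detected_in = detected_in,
               stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, rows)
  stats_df$adj_p <- adjust_bh(stats_df$p_value)
  stats_df$sig_class <- vapply(seq_len(nrow(stats_df)), function(i) {
    classify_significance(stats_df$log2_fc[i], stats_df$adj_p[i],
                          stats_df$is_pseudo_fc[i], stats_df$detected_in[i],
                          alpha = alpha, lfc_threshold = lfc_threshold)
  }, character(1))

  cls <- stats_df$sig_class
  summary <- list(
    first = first, second = second,
    total_quantified = nrow(stats_df),
    accumulated = sum(cls == "accumulated", na.rm = TRUE),
    depleted = sum(cls == "depleted", na.rm = TRUE),
    only_in_first = sum(cls == "only_in_first", na.rm = TRUE),
    only_in_second = sum(cls == "only_in_second", na.rm = TRUE),
    not_significant = sum(cls == "not_significant", na.rm = TRUE),
    unclassified = sum(is.na(cls))
  )
  structure(list(stats = stats_df, summary = summary,
                 first = first, second = second),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("comparison %s vs %s (second over first)\n", x$first, x$second))
  cat(sprintf("  quantified: %d\n  accumulated: %d  depleted: %d\n",
              s$total_quantified, s$accumulated, s$depleted))
  cat(sprintf("  only in %s: %d  only in %s: %d\n",
              x$first, s$only_in_first, x$second, s$only_in_second))
  invisible(x)
}
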