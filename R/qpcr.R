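# qPCR quantification from raw, background-subtracted amplification
# curves: window-of-linearity efficiency and Ct estimation per reaction,
# efficiency-corrected relative expression per the Pfaffl model against one
# or more reference genes (combined by geometric mean), and per-transition
# log2 fold-change tables.

#' Estimate amplification efficiency and threshold cycle from one curve
#'
#' Window-of-linearity approach: eligible cycles are those whose
#' fluorescence lies above a noise floor and below the plateau band (fixed
#' fractions of the curve maximum). Starting from the longest contiguous
#' eligible window and shrinking only if linearity fails, each candidate
#' window is fitted by linear regression of log2 fluorescence on cycle,
#' weighted by fluorescence squared (the inverse variance of log
#' fluorescence under additive instrument noise, so low-signal early
#' cycles do not dominate the slope); the longest window whose weighted
#' r-squared reaches `min_r_squared` defines the exponential phase. The
#' slope `b` gives the per-cycle efficiency `E = 2^b`, and the threshold
#' cycle is the fractional cycle where the fitted line crosses
#' `threshold_fraction * max(F)`.
#'
#' @param cycles Strictly increasing integer cycle numbers.
#' @param fluorescence Background-subtracted fluorescence values (>= 0).
#' @param threshold_fraction Threshold as a fraction of the maximum
#'   fluorescence (default 0.2).
#' @param min_window Minimum exponential-window length in cycles
#'   (default 4).
#' @param plateau_fraction Upper eligibility bound as a fraction of the
#'   maximum fluorescence (default 0.9, excluding the saturation band with
#'   a margin of many noise standard deviations at typical noise levels).
#' @param noise_floor_fraction Lower eligibility bound as a fraction of the
#'   maximum fluorescence (default 0.01).
#' @param min_r_squared Weighted r-squared a window must reach to be
#'   accepted (default 0.99); if no window reaches it, the best-fitting
#'   window is used and the result flagged low quality.
#' @return List of class `qpcr_fit`: `E`, `Ct`, `fit_window` (first and
#'   last cycle of the chosen window), `r_squared`, `low_quality`.
#'   Flat or sub-threshold curves are rejected with an error.
#' @export
#' @examples
#' curve <- simulate_qpcr_curve(E_true = 2, F0 = 1e-3, noise_sd = 0)
#' estimate_efficiency_ct(curve$cycle, curve$fluorescence)$E  # 2
estimate_efficiency_ct <- function(cycles, fluorescence,
                                   threshold_fraction = 0.2,
                                   min_window = 4,
                                   plateau_fraction = 0.9,
                                   noise_floor_fraction = 0.01,
                                   min_r_squared = 0.99) {
  if (length(cycles) != length(fluorescence))
    fail("`cycles` and `fluorescence` must have equal length")
  if (any(diff(cycles) <= 0)) fail("`cycles` must be strictly increasing")
  if (any(fluorescence < 0, na.rm = TRUE))
    fail("fluorescence must be background-subtracted and >= 0")
  fmax <- max(fluorescence)
  if (!is.finite(fmax) || fmax <= 0 ||
      fmax - min(fluorescence) < .Machine$double.eps * 100)
    fail("flat curve: no amplification signal")

  eligible <- fluorescence > noise_floor_fraction * fmax &
    fluorescence < plateau_fraction * fmax
  idx <- which(eligible)
  if (length(idx) < min_window)
    fail("fewer than %d cycles between noise floor and plateau", min_window)

  # weighted log-linear fit of one candidate window
  fit_window <- function(w) {
    x <- cycles[w]
    y <- log2(fluorescence[w])
    wt <- fluorescence[w]^2
    sw <- sqrt(wt)
    fit <- stats::lm.fit(cbind(sw, sw * x), sw * y)
    ss_res <- sum(fit$residuals^2)
    ybar <- sum(wt * y) / sum(wt)
    ss_tot <- sum(wt * (y - ybar)^2)
    r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
    list(r2 = r2, w = w, a = fit$coefficients[1], b = fit$coefficients[2])
  }

  # contiguous runs of eligible cycles; prefer the longest window whose
  # weighted r-squared clears the bar, shrinking only when linearity fails
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  runs <- runs[lengths(runs) >= min_window]
  if (!length(runs)) fail("no eligible window of length >= %d", min_window)
  best <- NULL
  accepted <- NULL
  for (len in seq(max(lengths(runs)), min_window)) {
    for (run in runs) {
      if (length(run) < len) next
      for (start in seq_len(length(run) - len + 1)) {
        cand <- fit_window(run[start:(start + len - 1)])
        if (is.null(best) || cand$r2 > best$r2) best <- cand
        if (cand$r2 >= min_r_squared &&
            (is.null(accepted) || cand$r2 > accepted$r2)) accepted <- cand
      }
    }
    if (!is.null(accepted)) break
  }
  if (!is.null(accepted)) best <- accepted
  if (best$b <= 0) fail("flat curve: non-increasing exponential phase")

  threshold <- threshold_fraction * fmax
  ct <- (log2(threshold) - best$a) / best$b
  structure(list(E = unname(2^best$b),
                 Ct = unname(ct),
                 fit_window = range(cycles[best$w]),
                 r_squared = best$r2,
                 low_quality = best$r2 < min_r_squared),
            class = "qpcr_fit")
}

#' Efficiency-corrected relative expression ratio (Pfaffl model)
#'
#' `ratio = E_target^dCt_target / E_ref^dCt_ref`, with each
#' `dCt = Ct(control) - Ct(sample)` so that induction in the sample gives a
#' ratio above 1. With both efficiencies equal to 2 this reduces to the
#' classical `2^-ddCt` value.
#'
#' @param E_target,E_ref Amplification efficiencies (> 1).
#' @param dCt_target,dCt_ref Threshold-cycle differences, control minus
#'   sample.
#' @return Positive ratio.
#' @export
#' @examples
#' pfaffl_ratio(2, 3, 2, 1)      # 4
#' pfaffl_ratio(1.9, 2, 2.0, 1)  # 1.805
pfaffl_ratio <- function(E_target, dCt_target, E_ref, dCt_ref) {
  if (!is_scalar_num(E_target) || E_target <= 1 ||
      !is_scalar_num(E_ref) || E_ref <= 1)
    fail("efficiencies must be > 1")
  E_target^dCt_target / E_ref^dCt_ref
}

#' Combine per-reference expression ratios
#'
#' Geometric mean of the ratios obtained against each reference gene (the
#' usual multi-reference normalization convention); with one reference the
#' ratio is returned unchanged.
#'
#' @param ratios_per_reference Positive numeric vector of ratios.
#' @return Combined ratio.
#' @export
#' @examples
#' combine_references(c(4, 1))  # 2
combine_references <- function(ratios_per_reference) {
  if (!length(ratios_per_reference)) fail("need at least one reference ratio")
  if (any(!is.finite(ratios_per_reference)) || any(ratios_per_reference <= 0))
    fail("ratios must be positive")
  geometric_mean(ratios_per_reference)
}

#' Fit every reaction of a long-format curve table
#'
#' @param curves Data.frame with columns `reaction`, `gene`, `sample`,
#'   `condition`, `cycle`, `fluorescence` (one row per cycle).
#' @param ... Passed to [estimate_efficiency_ct()].
#' @return Data.frame per reaction: `reaction`, `gene`, `sample`,
#'   `condition`, `E`, `Ct`, `r_squared`, `low_quality`.
#' @export
fit_qpcr_reactions <- function(curves, ...) {
  need <- c("reaction", "gene", "sample", "condition", "cycle", "fluorescence")
  if (!all(need %in% names(curves)))
    fail("`curves` needs columns: %s", paste(need, collapse = ", "))
  rows <- lapply(split(curves, curves$reaction), function(d) {
    d <- d[order(d$cycle), , drop = FALSE]
    fit <- estimate_efficiency_ct(d$cycle, d$fluorescence, ...)
    data.frame(reaction = d$reaction[1], gene = d$gene[1],
               sample = d$sample[1], condition = d$condition[1],
               E = fit$E, Ct = fit$Ct, r_squared = fit$r_squared,
               low_quality = fit$low_quality, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-transition relative expression via the Pfaffl model
#'
#' For each target gene and each transition (first condition ->
#' second condition), computes per-replicate Pfaffl ratios against the
#' first-condition mean Ct, combines the dual (or multiple) reference genes
#' by geometric mean, and reports the log2 of the geometric-mean
#' second-condition ratio (so reversing a transition exactly negates the
#' log2 fold change) with a two-tailed Welch t-test of the
#' second-condition replicate log-ratios against the first-condition ones.
#' Efficiencies are per-assay means across a gene's reactions.
#'
#' @param fits Per-reaction table from [fit_qpcr_reactions()].
#' @param targets Character vector of target gene names.
#' @param references Character vector of reference gene names (>= 1).
#' @param transitions List of `c(first, second)` condition pairs.
#' @return Long data.frame: `gene`, `first`, `second`, `ratio`
#'   (geometric-mean second-condition ratio), `log2_fc`, `p_value`,
#'   `stars`. Transitions lacking a condition are reported with `NA`
#'   values.
#' @export
relative_expression <- function(fits, targets, references, transitions) {
  if (!length(references)) fail("need at least one reference gene")
  missing_genes <- setdiff(c(targets, references), unique(fits$gene))
  if (length(missing_genes))
    fail("genes missing from fits: %s", paste(missing_genes, collapse = ", "))
  E_of <- vapply(split(fits$E, fits$gene), mean, numeric(1))

  # per-replicate combined ratio of `cond` vs the mean Ct of `ref_cond`
  ratios_vs <- function(gene, cond, ref_cond) {
    g <- fits[fits$gene == gene, , drop = FALSE]
    ct_ref_mean <- function(gn) {
      v <- fits$Ct[fits$gene == gn & fits$condition == ref_cond]
      if (!length(v)) return(NA_real_)
      mean(v)
    }
    rows <- g[g$condition == cond, , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    vapply(seq_len(nrow(rows)), function(i) {
      smp <- rows$sample[i]
      per_ref <- vapply(references, function(rg) {
        ct_rg <- fits$Ct[fits$gene == rg & fits$sample == smp]
        if (!length(ct_rg)) return(NA_real_)
        pfaffl_ratio(E_of[[gene]], ct_ref_mean(gene) - rows$Ct[i],
                     E_of[[rg]], ct_ref_mean(rg) - ct_rg[1])
      }, numeric(1))
      if (anyNA(per_ref)) return(NA_real_)
      combine_references(per_ref)
    }, numeric(1))
  }

  rows <- list()
  for (tr in transitions) {
    first <- tr[[1]]; second <- tr[[2]]
    for (gene in targets) {
      r2 <- ratios_vs(gene, second, first)
      r1 <- ratios_vs(gene, first, first)
      if (is.null(r1) || is.null(r2) || anyNA(c(r1, r2))) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, first = first, second = second,
          ratio = NA_real_, log2_fc = NA_real_, p_value = NA_real_,
          stars = NA_character_, stringsAsFactors = FALSE)
        next
      }
      p <- if (length(r1) >= 2 && length(r2) >= 2 &&
               (stats::var(log2(r1)) > 0 || stats::var(log2(r2)) > 0)) {
        stats::t.test(log2(r2), log2(r1))$p.value
      } else if (isTRUE(all.equal(mean(log2(r1)), mean(log2(r2))))) 1
      else NA_real_
      ratio <- geometric_mean(r2)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, first = first, second = second,
        ratio = ratio, log2_fc = log2(ratio),
        p_value = p, stars = p_stars(p), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
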