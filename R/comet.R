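# Comet-assay (single-cell gel electrophoresis) damage scoring. Nucleoids
# are visually assigned to damage classes 0 (intact) to 4 (maximal tail)
# upstream; this module aggregates class counts into the standard
# arbitrary-unit score and compares groups of slides.

#' Comet damage score in arbitrary units
#'
#' `a.u. = 100 * sum(N_c * c) / N_tot` over damage classes c = 0..4, where
#' `N_c` is the nucleoid count in class c and `N_tot` the total scored.
#' The score ranges from 0 (all intact) to 400 (all maximally damaged) and
#' is invariant under scaling all counts by a common factor.
#'
#' @param class_counts Either a length-5 vector of counts for classes 0-4,
#'   or a matrix/data.frame with 5 such columns (one row per slide).
#' @return Numeric score(s) in `[0, 400]`.
#' @export
#' @examples
#' comet_score(c(50, 20, 10, 10, 10))  # 110
comet_score <- function(class_counts) {
  if (is.data.frame(class_counts)) class_counts <- as.matrix(class_counts)
  if (is.matrix(class_counts)) {
    if (ncol(class_counts) != 5) fail("expected 5 class columns (classes 0-4)")
    return(apply(class_counts, 1, comet_score))
  }
  if (length(class_counts) != 5) fail("expected 5 class counts (classes 0-4)")
  if (any(!is.finite(class_counts)) || any(class_counts < 0))
    fail("class counts must be non-negative")
  n_tot <- sum(class_counts)
  if (n_tot == 0) fail("slide has zero scored nucleoids")
  100 * sum(class_counts * 0:4) / n_tot
}

#' Compare DNA damage between two groups of slides
#'
#' Two-tailed t-test (heteroscedastic/Welch by default) on per-slide
#' arbitrary-unit scores, with significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param slides_a,slides_b Matrices/data.frames of class counts (one slide
#'   per row, 5 class columns), or plain numeric vectors of precomputed
#'   per-slide scores.
#' @param var_equal Use pooled variance instead of Welch (default `FALSE`).
#' @return List with `mean_a`, `mean_b`, `t`, `df`, `p_value`, `stars`;
#'   `NA` fields when a group has fewer than two slides.
#' @export
compare_damage <- function(slides_a, slides_b, var_equal = FALSE) {
  score <- function(s) {
    if (is.numeric(s) && is.null(dim(s))) return(s)  # precomputed scores
    comet_score(s)
  }
  a <- score(slides_a)
  b <- score(slides_b)
  if (length(a) < 2 || length(b) < 2)
    return(list(mean_a = mean(a), mean_b = mean(b), t = NA_real_,
                df = NA_real_, p_value = NA_real_, stars = NA_character_))
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else NA_real_
    return(list(mean_a = mean(a), mean_b = mean(b),
                t = if (identical(p, 1)) 0 else NA_real_,
                df = NA_real_, p_value = p, stars = p_stars(p)))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(mean_a = mean(a), mean_b = mean(b),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, stars = p_stars(ht$p.value))
}
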