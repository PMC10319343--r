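# Germination indices from replicate time-course counts, following the
# classical germination-measurement formulary: germinability, mean
# germination time/rate, coefficient of velocity, uncertainty (entropy) and
# synchrony of the germination-time distribution, and interpolated T50.
# Indices are computed per replicate and then averaged across replicates,
# which is the convention that keeps group tables internally consistent
# (the group mean of 100/MGT is not 100/mean(MGT)).

check_counts <- function(new_germinations, time_points = NULL) {
  if (any(!is.finite(new_germinations)) || any(new_germinations < 0) ||
      any(new_germinations != round(new_germinations)))
    fail("`new_germinations` must be non-negative integer counts")
  if (!is.null(time_points)) {
    if (length(time_points) != length(new_germinations))
      fail("`time_points` and `new_germinations` must have equal length")
    if (any(diff(time_points) <= 0))
      fail("`time_points` must be strictly increasing")
  }
  invisible(TRUE)
}

#' Germinability (G, %)
#'
#' Final percentage of germinated seeds: `100 * sum(counts) / n_seeds`.
#'
#' @param new_germinations Integer counts of newly germinated seeds per
#'   observation interval.
#' @param n_seeds Total number of seeds sown (> 0).
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' germinability(c(9, 5, 2), n_seeds = 20)  # 80
germinability <- function(new_germinations, n_seeds) {
  check_counts(new_germinations)
  if (!is_count(n_seeds) || n_seeds < 1) fail("`n_seeds` must be > 0")
  total <- sum(new_germinations)
  if (total > n_seeds) fail("germinated count exceeds `n_seeds`")
  100 * total / n_seeds
}

#' Mean germination time (MGT, days)
#'
#' Count-weighted mean of the observation times:
#' `sum(n_i t_i) / sum(n_i)`, with `t_i` the time at which the interval's
#' germinations were recorded (interval endpoints).
#'
#' @inheritParams germinability
#' @param time_points Strictly increasing observation times (days).
#' @return Days, or `NA` if no seed germinated.
#' @export
#' @examples
#' mean_germination_time(c(5, 10, 5), c(1, 2, 3))  # 2
mean_germination_time <- function(new_germinations, time_points) {
  check_counts(new_germinations, time_points)
  total <- sum(new_germinations)
  if (total == 0) return(NA_real_)
  sum(new_germinations * time_points) / total
}

#' Mean germination rate and coefficient of velocity
#'
#' Per replicate, `MGR = 1/MGT` (day^-1) and `CVG = 100/MGT` (%); group
#' values are the arithmetic means of the per-replicate indices (note the
#' Jensen gap: `mean(1/MGT) != 1/mean(MGT)`).
#'
#' @param mgt_per_replicate Numeric vector of per-replicate MGT values
#'   (`NA` for replicates without germinations).
#' @return List with per-replicate `mgr` and `cvg` vectors and group means
#'   `mean_mgr`, `mean_cvg`.
#' @export
rate_indices <- function(mgt_per_replicate) {
  if (any(mgt_per_replicate <= 0, na.rm = TRUE)) fail("MGT must be > 0")
  mgr <- 1 / mgt_per_replicate
  cvg <- 100 / mgt_per_replicate
  list(mgr = mgr, cvg = cvg,
       mean_mgr = mean(mgr, na.rm = TRUE),
       mean_cvg = mean(cvg, na.rm = TRUE))
}

#' Uncertainty of the germination-time distribution (U, bits)
#'
#' Shannon entropy (log base 2) of the relative germination frequencies
#' over the observation intervals: `U = -sum(f_i log2 f_i)` over intervals
#' with germinations. 0 bits means all seeds germinated in one interval.
#'
#' @inheritParams germinability
#' @return Bits (>= 0), or `NA` if no seed germinated.
#' @export
#' @examples
#' uncertainty_index(c(5, 15))  # -0.25*log2(0.25) - 0.75*log2(0.75)
uncertainty_index <- function(new_germinations) {
  check_counts(new_germinations)
  total <- sum(new_germinations)
  if (total == 0) return(NA_real_)
  f <- new_germinations[new_germinations > 0] / total
  -sum(f * log2(f))
}

#' Synchronization index (Z)
#'
#' Probability that two randomly chosen germinated seeds germinated in the
#' same interval: `Z = sum(C(n_i, 2)) / C(sum(n_i), 2)`, in `[0, 1]`; 1
#' means perfectly synchronous germination.
#'
#' @inheritParams germinability
#' @return Value in `[0, 1]`, or `NA` with fewer than two germinations.
#' @export
#' @examples
#' synchrony_index(c(5, 5))  # 20/45
synchrony_index <- function(new_germinations) {
  check_counts(new_germinations)
  total <- sum(new_germinations)
  if (total < 2) return(NA_real_)
  sum(choose(new_germinations, 2)) / choose(total, 2)
}

#' Time to 50% of final germination (T50, days)
#'
#' The time at which the cumulative germination curve reaches half of its
#' final value, linearly interpolated between the bracketing observation
#' times. If half of the final count is already reached at the first
#' observation (no bracketing interval), that boundary time is returned
#' with attribute `boundary = TRUE`.
#'
#' @inheritParams mean_germination_time
#' @return Days (possibly with attribute `boundary`), or `NA` if nothing
#'   germinated.
#' @export
#' @examples
#' t50(c(0, 5, 15), c(0, 1, 2))  # 1 + (10 - 5)/15
t50 <- function(new_germinations, time_points) {
  check_counts(new_germinations, time_points)
  cum <- cumsum(new_germinations)
  final <- cum[length(cum)]
  if (final == 0) return(NA_real_)
  half <- final / 2
  i <- which(cum >= half)[1]
  if (i == 1L) {
    # half of the final count already reached at the first observation:
    # no bracketing interval, return the boundary time flagged
    out <- time_points[1]
    attr(out, "boundary") <- TRUE
    return(out)
  }
  time_points[i - 1] +
    (half - cum[i - 1]) / (cum[i] - cum[i - 1]) *
      (time_points[i] - time_points[i - 1])
}

#' Signed percent change relative to a reference
#'
#' `100 * (value - reference) / reference`; negative values are decreases.
#'
#' @param reference Reference (e.g. untreated group mean); must be nonzero.
#' @param value Comparison value (e.g. treated group mean).
#' @return Signed percentage.
#' @export
#' @examples
#' percent_change(47.00, 73.00)  # +55.32
#' percent_change(1.64, 1.17)    # -28.66
percent_change <- function(reference, value) {
  if (!is_scalar_num(reference) || reference == 0)
    fail("`reference` must be a nonzero number")
  if (!is_scalar_num(value)) fail("`value` must be a number")
  100 * (value - reference) / reference
}

#' Per-replicate germination indices from a count table
#'
#' Computes G, MGT, MGR, CVG, U, Z and T50 for every replicate of a
#' germination count table.
#'
#' @param counts Data.frame with columns `replicate`, `time_days`,
#'   `new_germinations`, `n_seeds` (as produced by
#'   [simulate_germination_counts()] or read from a counts CSV).
#' @return A data.frame with one row per replicate and columns `replicate`,
#'   `G`, `MGT`, `MGR`, `CVG`, `U`, `Z`, `T50`.
#' @export
germination_indices <- function(counts) {
  need <- c("replicate", "time_days", "new_germinations", "n_seeds")
  if (!all(need %in% names(counts)))
    fail("`counts` needs columns: %s", paste(need, collapse = ", "))
  reps <- unique(counts$replicate)
  rows <- lapply(reps, function(r) {
    d <- counts[counts$replicate == r, , drop = FALSE]
    d <- d[order(d$time_days), , drop = FALSE]
    mgt <- mean_germination_time(d$new_germinations, d$time_days)
    data.frame(replicate = r,
               G = germinability(d$new_germinations, d$n_seeds[1]),
               MGT = mgt,
               MGR = if (is.na(mgt)) NA_real_ else 1 / mgt,
               CVG = if (is.na(mgt)) NA_real_ else 100 / mgt,
               U = uncertainty_index(d$new_germinations),
               Z = synchrony_index(d$new_germinations),
               T50 = as.numeric(t50(d$new_germinations, d$time_days)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare two groups of germination indices
#'
#' Per index, a two-tailed heteroscedastic (Welch) Student's t-test across
#' replicates, with group means, standard deviations, and significance
#' stars at 0.05 / 0.01 / 0.001.
#'
#' @param indices_a,indices_b Per-replicate index tables from
#'   [germination_indices()] (group A is the reference for the reported
#'   percent change).
#' @param var_equal Use pooled variance instead of Welch (default `FALSE`).
#' @return A data.frame per index: means, SDs, `percent_change` (B vs A),
#'   `t`, `df`, `p_value`, `stars`.
#' @export
compare_germination <- function(indices_a, indices_b, var_equal = FALSE) {
  idx <- setdiff(intersect(names(indices_a), names(indices_b)), "replicate")
  rows <- lapply(idx, function(v) {
    a <- indices_a[[v]]; b <- indices_b[[v]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) {
      tt <- list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
    } else if (stats::var(a) == 0 && stats::var(b) == 0) {
      eq <- isTRUE(all.equal(mean(a), mean(b)))
      tt <- list(statistic = if (eq) 0 else NA_real_,
                 parameter = NA_real_, p.value = if (eq) 1 else NA_real_)
    } else {
      ht <- stats::t.test(a, b, var.equal = var_equal)
      tt <- list(statistic = unname(ht$statistic),
                 parameter = unname(ht$parameter), p.value = ht$p.value)
    }
    data.frame(index = v,
               mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b),
               percent_change = if (mean(a) != 0)
                 percent_change(mean(a), mean(b)) else NA_real_,
               t = tt$statistic, df = tt$parameter, p_value = tt$p.value,
               stars = p_stars(tt$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
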