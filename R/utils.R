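# Internal helpers shared across modules.

#' Evaluate code with a local, explicitly seeded RNG stream
#'
#' Seeds the generator, evaluates `code`, and restores the caller's RNG
#' state afterwards, so simulations are reproducible without mutating
#' global state.
#'
#' @param seed Single integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_preserved_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Significance stars for a p-value
#'
#' Conventional star coding: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' otherwise the empty string. `NA` maps to `NA`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of the same length.
#' @export
#' @examples
#' p_stars(c(0.2, 0.04, 0.004, 0.0004))
p_stars <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 0.001, "***",
             ifelse(p[ok] < 0.01, "**",
             ifelse(p[ok] < 0.05, "*", "")))
  out
}

# Geometric mean of strictly positive values.
geometric_mean <- function(x) {
  stopifnot(all(is.finite(x)), all(x > 0))
  exp(mean(log(x)))
}

# Stop with a formatted message, without the call in the condition.
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
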