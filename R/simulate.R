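# Synthetic-data generators. Each generator draws from its own explicitly
# seeded stream and restores the caller's RNG state, so a given seed always
# produces the identical dataset regardless of surrounding code.

#' Configuration for a simulated label-free proteome experiment
#'
#' Describes a protein x sample intensity experiment on the log2 scale:
#' every intensity is `2^(baseline + condition effect + Normal(0, sd))`,
#' with two missingness mechanisms layered on top: sporadic
#' missing-completely-at-random dropout, and condition-wise complete absence
#' for selected (protein, condition) pairs (emulating proteins detected in
#' only one condition of a comparison).
#'
#' @param n_proteins Number of simulated protein groups.
#' @param conditions Character vector of condition labels.
#' @param n_replicates_per_condition Replicates per condition (default 5,
#'   the design of the emulated experiment).
#' @param log2_effect_sizes Optional numeric matrix of log2 shifts relative
#'   to baseline, `n_proteins` rows x `length(conditions)` columns (colnames
#'   must be the condition labels if set). `NULL` = no effects.
#' @param baseline_log2_mean Baseline log2 intensity (default 20, i.e. about
#'   1e6 on the raw scale, a typical LFQ magnitude).
#' @param replicate_sd Replicate standard deviation on the log2 scale
#'   (default 0.5).
#' @param sporadic_missing_rate Probability in `[0, 1]` that any single
#'   measurement drops out at random.
#' @param absent_pairs Optional data.frame with columns `protein` (ID or row
#'   index) and `condition`; all intensities of those pairs are forced to 0.
#' @param seed Integer seed for the generator stream.
#' @return A validated list of class `proteome_sim_config`.
#' @seealso [simulate_intensity_table()]
#' @export
proteome_sim_config <- function(n_proteins,
                                conditions,
                                n_replicates_per_condition = 5,
                                log2_effect_sizes = NULL,
                                baseline_log2_mean = 20,
                                replicate_sd = 0.5,
                                sporadic_missing_rate = 0,
                                absent_pairs = NULL,
                                seed = 1) {
  if (!is_count(n_proteins) || n_proteins < 1) fail("`n_proteins` must be a positive count")
  conditions <- as.character(conditions)
  if (length(conditions) < 1 || anyDuplicated(conditions))
    fail("`conditions` must be distinct labels")
  if (!is_count(n_replicates_per_condition) || n_replicates_per_condition < 2)
    fail("`n_replicates_per_condition` must be >= 2")
  if (!is_scalar_num(replicate_sd) || replicate_sd <= 0)
    fail("`replicate_sd` must be > 0")
  if (!is_scalar_num(sporadic_missing_rate) ||
      sporadic_missing_rate < 0 || sporadic_missing_rate > 1)
    fail("`sporadic_missing_rate` must be in [0, 1]")
  if (!is_scalar_num(baseline_log2_mean)) fail("`baseline_log2_mean` must be numeric")
  if (!is.null(log2_effect_sizes)) {
    if (!is.matrix(log2_effect_sizes) ||
        nrow(log2_effect_sizes) != n_proteins ||
        ncol(log2_effect_sizes) != length(conditions))
      fail("`log2_effect_sizes` must be an n_proteins x n_conditions matrix")
    if (!is.null(colnames(log2_effect_sizes)) &&
        !identical(colnames(log2_effect_sizes), conditions))
      fail("`log2_effect_sizes` colnames must match `conditions`")
  }
  if (!is.null(absent_pairs)) {
    if (!is.data.frame(absent_pairs) ||
        !all(c("protein", "condition") %in% names(absent_pairs)))
      fail("`absent_pairs` needs columns `protein` and `condition`")
    if (!all(absent_pairs$condition %in% conditions))
      fail("`absent_pairs` refers to unknown conditions")
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         conditions = conditions,
         n_replicates_per_condition = as.integer(n_replicates_per_condition),
         log2_effect_sizes = log2_effect_sizes,
         baseline_log2_mean = baseline_log2_mean,
         replicate_sd = replicate_sd,
         sporadic_missing_rate = sporadic_missing_rate,
         absent_pairs = absent_pairs,
         seed = as.integer(seed)),
    class = "proteome_sim_config"
  )
}

#' Simulate a label-free protein intensity table
#'
#' Draws intensities as `2^(baseline + effect + Normal(0, sd))`, applies
#' sporadic dropout, zeroes out the configured absent (protein, condition)
#' pairs, and draws peptide counts (1 + Poisson(4)). Protein IDs are
#' `P0001`, `P0002`, ... and samples `<condition>_r<k>`.
#'
#' @param cfg A [proteome_sim_config()].
#' @return An [intensity_table()].
#' @export
#' @examples
#' cfg <- proteome_sim_config(50, c("UP2", "PRH2"), seed = 42)
#' simulate_intensity_table(cfg)
simulate_intensity_table <- function(cfg) {
  if (!inherits(cfg, "proteome_sim_config"))
    fail("`cfg` must come from proteome_sim_config()")
  with_preserved_seed(cfg$seed, {
    n <- cfg$n_proteins
    protein_ids <- sprintf("P%04d", seq_len(n))
    samples <- as.vector(vapply(
      cfg$conditions,
      function(cd) paste0(cd, "_r", seq_len(cfg$n_replicates_per_condition)),
      character(cfg$n_replicates_per_condition)))
    condition_of <- rep(cfg$conditions, each = cfg$n_replicates_per_condition)
    names(condition_of) <- samples

    eff <- matrix(0, n, length(cfg$conditions),
                  dimnames = list(protein_ids, cfg$conditions))
    if (!is.null(cfg$log2_effect_sizes)) {
      e <- cfg$log2_effect_sizes
      colnames(e) <- cfg$conditions
      eff[] <- e
    }

    log2_means <- cfg$baseline_log2_mean + eff[, condition_of, drop = FALSE]
    noise <- matrix(stats::rnorm(n * length(samples), 0, cfg$replicate_sd),
                    n, length(samples))
    x <- 2^(log2_means + noise)
    dimnames(x) <- list(protein_ids, samples)

    if (cfg$sporadic_missing_rate > 0) {
      drop <- matrix(stats::runif(n * length(samples)) < cfg$sporadic_missing_rate,
                     n, length(samples))
      x[drop] <- 0
    }
    if (!is.null(cfg$absent_pairs)) {
      for (i in seq_len(nrow(cfg$absent_pairs))) {
        pid <- cfg$absent_pairs$protein[i]
        if (is.numeric(pid)) pid <- protein_ids[pid]
        if (!pid %in% protein_ids) fail("absent pair refers to unknown protein %s", pid)
        x[pid, condition_of == cfg$absent_pairs$condition[i]] <- 0
      }
    }
    peptide_counts <- 1L + stats::rpois(n, 4)
    names(peptide_counts) <- protein_ids
    intensity_table(x, peptide_counts, condition_of)
  })
}

#' Configuration for a simulated germination time course
#'
#' Germination is modelled as a discrete-time survival process: in each
#' observation interval every still-ungerminated seed germinates
#' independently with that interval's hazard, so new germinations per
#' interval are binomial draws from the remaining seeds.
#'
#' @param n_replicates Number of replicate dishes (default 3).
#' @param n_seeds Seeds sown per replicate (default 20).
#' @param daily_germination_probs Per-interval germination hazards in
#'   `[0, 1]`, one per time point.
#' @param time_points Strictly increasing observation times (days).
#' @param seed Integer seed.
#' @return A validated list of class `germination_sim_config`.
#' @export
germination_sim_config <- function(n_replicates = 3,
                                   n_seeds = 20,
                                   daily_germination_probs,
                                   time_points = seq_along(daily_germination_probs),
                                   seed = 1) {
  if (!is_count(n_replicates) || n_replicates < 1) fail("`n_replicates` must be >= 1")
  if (!is_count(n_seeds) || n_seeds < 1) fail("`n_seeds` must be >= 1")
  if (!is.numeric(daily_germination_probs) ||
      any(!is.finite(daily_germination_probs)) ||
      any(daily_germination_probs < 0 | daily_germination_probs > 1))
    fail("hazards must be probabilities in [0, 1]")
  if (length(time_points) != length(daily_germination_probs))
    fail("`time_points` and hazards must have equal length")
  if (any(diff(time_points) <= 0)) fail("`time_points` must be strictly increasing")
  structure(
    list(n_replicates = as.integer(n_replicates),
         n_seeds = as.integer(n_seeds),
         daily_germination_probs = daily_germination_probs,
         time_points = as.numeric(time_points),
         seed = as.integer(seed)),
    class = "germination_sim_config"
  )
}

#' Simulate germination count tables
#'
#' @param cfg A [germination_sim_config()].
#' @return A data.frame with columns `replicate`, `time_days`,
#'   `new_germinations`, `n_seeds` (one row per replicate x time point).
#' @export
#' @examples
#' cfg <- germination_sim_config(daily_germination_probs = c(0.4, 0.6, 0.5),
#'                               seed = 7)
#' simulate_germination_counts(cfg)
simulate_germination_counts <- function(cfg) {
  if (!inherits(cfg, "germination_sim_config"))
    fail("`cfg` must come from germination_sim_config()")
  with_preserved_seed(cfg$seed, {
    rows <- lapply(seq_len(cfg$n_replicates), function(r) {
      remaining <- cfg$n_seeds
      new <- integer(length(cfg$time_points))
      for (i in seq_along(cfg$time_points)) {
        new[i] <- stats::rbinom(1, remaining, cfg$daily_germination_probs[i])
        remaining <- remaining - new[i]
      }
      data.frame(replicate = paste0("rep", r),
                 time_days = cfg$time_points,
                 new_germinations = new,
                 n_seeds = cfg$n_seeds)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a background-subtracted qPCR amplification curve
#'
#' Fluorescence follows exponential amplification `F0 * E^cycle`, saturates
#' at `plateau`, and gains additive Gaussian noise floored at zero.
#'
#' @param E_true True per-cycle amplification efficiency, in `(1, 2]`.
#' @param F0 Initial fluorescence-equivalent template signal (> 0).
#' @param n_cycles Number of cycles (default 45, matching common protocols).
#' @param noise_sd Additive noise standard deviation (>= 0).
#' @param plateau Saturation fluorescence (> 0).
#' @param seed Integer seed.
#' @return A data.frame with columns `cycle`, `fluorescence`.
#' @export
#' @examples
#' simulate_qpcr_curve(E_true = 1.95, F0 = 1e-6, seed = 3)
simulate_qpcr_curve <- function(E_true, F0, n_cycles = 45, noise_sd = 0,
                                plateau = 3, seed = 1) {
  if (!is_scalar_num(E_true) || E_true <= 1 || E_true > 2)
    fail("`E_true` must be in (1, 2]")
  if (!is_scalar_num(F0) || F0 <= 0) fail("`F0` must be > 0")
  if (!is_count(n_cycles) || n_cycles < 1) fail("`n_cycles` must be a positive count")
  if (!is_scalar_num(noise_sd) || noise_sd < 0) fail("`noise_sd` must be >= 0")
  if (!is_scalar_num(plateau) || plateau <= 0) fail("`plateau` must be > 0")
  with_preserved_seed(seed, {
    cycles <- seq_len(n_cycles)
    f <- pmin(F0 * E_true^cycles, plateau)
    if (noise_sd > 0) f <- f + stats::rnorm(n_cycles, 0, noise_sd)
    data.frame(cycle = cycles, fluorescence = pmax(f, 0))
  })
}

#' Simulate comet-assay nucleoid class counts
#'
#' One multinomial draw over damage classes 0-4 for a slide of
#' `n_nucleoids` scored nucleoids.
#'
#' @param class_probs Probability vector of length 5 (classes 0-4), summing
#'   to 1 within 1e-9.
#' @param n_nucleoids Nucleoids scored per slide (default 100, the usual
#'   scoring convention).
#' @param seed Integer seed.
#' @return Named integer vector `c0`..`c4` summing to `n_nucleoids`.
#' @export
#' @examples
#' simulate_comet_counts(c(0.5, 0.25, 0.12, 0.08, 0.05), seed = 11)
simulate_comet_counts <- function(class_probs, n_nucleoids = 100, seed = 1) {
  if (!is.numeric(class_probs) || length(class_probs) != 5 ||
      any(!is.finite(class_probs)) || any(class_probs < 0))
    fail("`class_probs` must be 5 non-negative probabilities (classes 0-4)")
  if (abs(sum(class_probs) - 1) > 1e-9)
    fail("`class_probs` must sum to 1 (tolerance 1e-9)")
  if (!is_count(n_nucleoids) || n_nucleoids < 1)
    fail("`n_nucleoids` must be a positive count")
  with_preserved_seed(seed, {
    counts <- as.integer(stats::rmultinom(1, n_nucleoids, class_probs))
    names(counts) <- paste0("c", 0:4)
    counts
  })
}
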