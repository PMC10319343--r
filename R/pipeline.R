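# End-to-end orchestration: simulate (or load) every input, run the
# differential-abundance comparisons of the declared experimental design,
# preranked enrichment, the physiology modules, and the cross-layer
# correlation; write per-stage CSVs, a count summary JSON mirroring the
# comparison-table layout, and a run log. Outputs are a pure function of
# (config, seed).

#' Default pipeline configuration
#'
#' Declares the full experimental design of the emulated study: eight
#' seed states along the rehydration-dehydration cycle (dry seed DS;
#' primed P; dry-back PDB2/PDB4; post-priming rehydration PRH2/PRH8;
#' unprimed imbibition UP2/UP8), the ten pairwise transitions analysed
#' between them, and desk-scale synthetic-data settings for each module
#' (sizes chosen so a full run stays light while every downstream
#' statistic remains estimable).
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  conditions <- c("DS", "P", "PDB2", "PDB4", "PRH2", "PRH8", "UP2", "UP8")
  comparisons <- list(
    c("DS", "P"), c("P", "PDB2"), c("PDB2", "PDB4"), c("PDB4", "PRH2"),
    c("PRH2", "PRH8"), c("DS", "UP2"), c("UP2", "UP8"), c("DS", "PDB4"),
    c("UP2", "PRH2"), c("UP8", "PRH8"))
  # log2 expression shifts of the qPCR target genes per condition; the
  # mapped proteins receive the same shifts so the two layers correlate
  gene_effects <- rbind(
    ITPA   = c(DS = 0, P = 0, PDB2 = 0, PDB4 = 0, PRH2 = 2,  PRH8 = 2,  UP2 = 0,  UP8 = 0),
    TRXm4  = c(DS = 0, P = 0, PDB2 = 1, PDB4 = -1, PRH2 = 0, PRH8 = 0,  UP2 = 0,  UP8 = 0),
    DRP2B  = c(DS = 0, P = 1.5, PDB2 = 1.5, PDB4 = 0, PRH2 = 0, PRH8 = 0, UP2 = 0, UP8 = 0),
    ASPG1  = c(DS = 0, P = 0, PDB2 = 0, PDB4 = 0, PRH2 = 1.5, PRH8 = 0, UP2 = 0, UP8 = 1),
    RS2Z32 = c(DS = 0, P = 0, PDB2 = 0, PDB4 = 1, PRH2 = 0,  PRH8 = 1.5, UP2 = 0, UP8 = 0))
  list(
    seed = as.integer(seed),
    conditions = conditions,
    comparisons = comparisons,
    proteome = list(n_proteins = 600, n_replicates = 5,
                    baseline_log2_mean = 20, replicate_sd = 0.5,
                    sporadic_missing_rate = 0.03,
                    n_spiked = 20, spike_log2 = 2.5, n_absent = 4),
    gene_effects = gene_effects,
    gene_sets = list(n_random_sets = 12, set_size = 25),
    gsea = list(n_perm = 200, weight_exponent = 1),
    thresholds = list(min_peptides = 2, max_missing = 4,
                      alpha = 0.05, lfc = 1),
    # hazards chosen so the expected indices emulate the unprimed vs
    # hydroprimed contrast (UP: G ~ 0.85, MGT ~ 1.66 d; P: G ~ 0.85,
    # MGT ~ 1.25 d)
    germination = list(
      n_replicates = 3, n_seeds = 20, time_points = 1:4,
      hazards = list(UP = c(0.45, 0.50, 0.30, 0.20),
                     P = c(0.70, 0.35, 0.15, 0.10))),
    comet = list(
      n_slides = 3, n_nucleoids = 100,
      class_probs = list(
        "UP-dI" = c(0.55, 0.25, 0.12, 0.05, 0.03),
        "UP+dI" = c(0.25, 0.25, 0.20, 0.18, 0.12),
        "P-dI"  = c(0.55, 0.25, 0.12, 0.05, 0.03),
        "P+dI"  = c(0.45, 0.25, 0.15, 0.10, 0.05)),
      compare = list(c("UP-dI", "UP+dI"), c("P-dI", "P+dI"),
                     c("UP-dI", "P-dI"), c("UP+dI", "P+dI"))),
    qpcr = list(
      references = c("ELF1a", "ACT"), E_true = 1.95, F0_base = 5e-7,
      n_replicates = 3, noise_sd = 0.005, plateau = 3, n_cycles = 45,
      conditions = c("PDB4", "PRH2", "PRH8", "UP2", "UP8"),
      transitions = list(c("PDB4", "PRH2"), c("PRH2", "PRH8"),
                         c("UP2", "PRH2"), c("UP8", "PRH8")))
  )
}

validate_pipeline_config <- function(config) {
  need <- c("seed", "conditions", "comparisons", "proteome", "gene_effects",
            "gene_sets", "gsea", "thresholds", "germination", "comet", "qpcr")
  missing_f <- setdiff(need, names(config))
  if (length(missing_f))
    fail("config is missing fields: %s", paste(missing_f, collapse = ", "))
  for (cmp in config$comparisons) {
    bad <- setdiff(cmp, config$conditions)
    if (length(bad))
      fail("comparison refers to undeclared condition(s): %s",
           paste(bad, collapse = ", "))
  }
  bad_q <- setdiff(unlist(config$qpcr$transitions), config$qpcr$conditions)
  if (length(bad_q))
    fail("qPCR transition refers to undeclared condition(s): %s",
         paste(bad_q, collapse = ", "))
  if (!identical(colnames(config$gene_effects), config$conditions))
    fail("gene_effects columns must match the declared conditions")
  invisible(TRUE)
}

# Build the proteome effect matrix: qPCR target genes mapped onto the
# first proteins, then generic spiked proteins, then condition-absent ones.
build_proteome_design <- function(config) {
  pr <- config$proteome
  n <- pr$n_proteins
  conditions <- config$conditions
  eff <- matrix(0, n, length(conditions),
                dimnames = list(sprintf("P%04d", seq_len(n)), conditions))
  genes <- rownames(config$gene_effects)
  gene_protein <- stats::setNames(sprintf("P%04d", seq_along(genes)), genes)
  eff[seq_along(genes), ] <- config$gene_effects

  spike_rows <- seq(length(genes) + 1, length.out = pr$n_spiked)
  spiked_ids <- rownames(eff)[spike_rows]
  # alternate up/down spikes in the PRH2 condition (post-priming imbibition)
  spike_sign <- rep(c(1, -1), length.out = pr$n_spiked)
  eff[spike_rows, "PRH2"] <- spike_sign * pr$spike_log2

  absent_rows <- seq(max(spike_rows) + 1, length.out = pr$n_absent)
  # condition-absent proteins are abundant (well above the pseudo-count
  # floor) so their pseudo fold changes clear the reporting threshold
  eff[absent_rows, ] <- 2
  absent <- data.frame(protein = rownames(eff)[absent_rows],
                       condition = rep(c("PRH2", "UP2"),
                                       length.out = pr$n_absent),
                       stringsAsFactors = FALSE)
  list(effects = eff, gene_protein = gene_protein,
       spiked_ids = spiked_ids,
       spiked_up_ids = spiked_ids[spike_sign > 0],
       spiked_down_ids = spiked_ids[spike_sign < 0],
       absent_pairs = absent)
}

# Synthetic gene-set collection over the simulated protein IDs: two
# directionally coherent sets holding the up- and down-spiked proteins
# (a set mixing both directions would cancel in the running sum), plus
# random sets.
build_gene_sets <- function(protein_ids, spiked_up_ids, spiked_down_ids,
                            n_random_sets, set_size, seed) {
  with_preserved_seed(seed, {
    sets <- lapply(seq_len(n_random_sets), function(i) {
      members <- sample(protein_ids, set_size)
      attr(members, "description") <- sprintf("random set %d", i)
      members
    })
    names(sets) <- sprintf("GO_RANDOM_%02d", seq_len(n_random_sets))
    up <- spiked_up_ids
    attr(up, "description") <- "proteins accumulated during post-priming imbibition"
    down <- spiked_down_ids
    attr(down, "description") <- "proteins depleted during post-priming imbibition"
    sets$GO_PRIMING_ACCUMULATED <- up
    sets$GO_PRIMING_DEPLETED <- down
    sets
  })
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    fail("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> differential abundance per declared comparison ->
#' preranked enrichment -> germination, comet and qPCR stages ->
#' transcript-protein correlation, writing per-stage CSVs, a summary JSON
#' with the per-comparison protein counts, and a run log. All randomness
#' is derived from `config$seed`, so a rerun with the same configuration
#' reproduces every output byte for byte.
#'
#' @param config Configuration list (see [default_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results
#'   (`comparisons`, `gsea`, `ora`, `germination`, `comet`, `qpcr`,
#'   `correlation`, `summary`) and `out_dir`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  log_lines <- c(sprintf("seedcycle pipeline, seed %d", config$seed),
                 sprintf("conditions: %s", paste(config$conditions, collapse = ", ")))

  ## ---- proteome ----
  design <- build_proteome_design(config)
  table <- run_stage("simulate_proteome", {
    cfg <- proteome_sim_config(
      n_proteins = config$proteome$n_proteins,
      conditions = config$conditions,
      n_replicates_per_condition = config$proteome$n_replicates,
      log2_effect_sizes = design$effects,
      baseline_log2_mean = config$proteome$baseline_log2_mean,
      replicate_sd = config$proteome$replicate_sd,
      sporadic_missing_rate = config$proteome$sporadic_missing_rate,
      absent_pairs = design$absent_pairs,
      seed = config$seed + 101L)
    simulate_intensity_table(cfg)
  })
  # round-trip through the on-disk dialect so the run exercises the readers
  tsv <- file.path(out_dir, "protein_groups.tsv")
  write_intensity_table(table, tsv)
  table <- read_protein_groups(tsv, design = data.frame(
    sample = names(table$condition_of),
    condition = unname(table$condition_of), stringsAsFactors = FALSE))

  gene_sets <- run_stage("gene_sets", {
    sets <- build_gene_sets(rownames(table$intensities),
                            design$spiked_up_ids, design$spiked_down_ids,
                            config$gene_sets$n_random_sets,
                            config$gene_sets$set_size,
                            seed = config$seed + 202L)
    gmt <- file.path(out_dir, "gene_sets.gmt")
    write_gmt(sets, gmt)
    read_gmt(gmt)
  })

  comparisons <- list()
  gsea_rows <- list()
  summary_rows <- list()
  for (i in seq_along(config$comparisons)) {
    cmp <- config$comparisons[[i]]
    label <- paste0(cmp[1], "_vs_", cmp[2])
    res <- run_stage(paste0("diffabund_", label), {
      run_comparison(table, cmp[1], cmp[2],
                     min_peptides = th$min_peptides,
                     max_missing = th$max_missing,
                     alpha = th$alpha, lfc_threshold = th$lfc)
    })
    comparisons[[label]] <- res
    write_results_table(res$stats,
                        file.path(out_dir, paste0("diffabund_", label, ".csv")))
    summary_rows[[label]] <- data.frame(
      comparison = label, first = cmp[1], second = cmp[2],
      total_quantified = res$summary$total_quantified,
      accumulated = res$summary$accumulated,
      depleted = res$summary$depleted,
      only_in_first = res$summary$only_in_first,
      only_in_second = res$summary$only_in_second,
      stringsAsFactors = FALSE)

    g <- run_stage(paste0("gsea_", label), {
      st <- res$stats
      ranked <- st[!is.na(st$t_stat), ]
      scores <- stats::setNames(ranked$t_stat, ranked$protein_id)
      gsea_preranked(scores, gene_sets,
                     n_perm = config$gsea$n_perm,
                     seed = config$seed + 303L + i,
                     weight_exponent = config$gsea$weight_exponent)
    })
    if (nrow(g)) {
      g$comparison <- label
      gsea_rows[[label]] <- g
    }
  }
  summary_df <- do.call(rbind, summary_rows)
  rownames(summary_df) <- NULL
  write_results_table(summary_df, file.path(out_dir, "comparison_summary.csv"))
  gsea_df <- do.call(rbind, gsea_rows)
  rownames(gsea_df) <- NULL
  write_results_table(gsea_df, file.path(out_dir, "gsea_results.csv"))

  ora <- run_stage("ora", {
    focal <- comparisons[["UP2_vs_PRH2"]]
    if (is.null(focal)) focal <- comparisons[[1]]
    sig <- focal$stats$protein_id[!is.na(focal$stats$sig_class) &
                                    focal$stats$sig_class != "not_significant"]
    hypergeometric_enrichment(sig, focal$stats$protein_id, gene_sets)
  })
  write_results_table(ora, file.path(out_dir, "ora_results.csv"))

  ## ---- germination ----
  germ <- run_stage("germination", {
    groups <- names(config$germination$hazards)
    idx <- lapply(seq_along(groups), function(k) {
      cfg <- germination_sim_config(
        n_replicates = config$germination$n_replicates,
        n_seeds = config$germination$n_seeds,
        daily_germination_probs = config$germination$hazards[[k]],
        time_points = config$germination$time_points,
        seed = config$seed + 404L + k)
      counts <- simulate_germination_counts(cfg)
      cbind(group = groups[k], germination_indices(counts),
            stringsAsFactors = FALSE)
    })
    names(idx) <- groups
    indices <- do.call(rbind, idx)
    comparison <- compare_germination(idx[[1]][-1], idx[[2]][-1])
    list(indices = indices, comparison = comparison,
         reference = groups[1], treated = groups[2])
  })
  write_results_table(germ$indices, file.path(out_dir, "germination_indices.csv"))
  write_results_table(germ$comparison,
                      file.path(out_dir, "germination_comparison.csv"))

  ## ---- comet ----
  comet <- run_stage("comet", {
    cc <- config$comet
    slides <- list()
    for (g in names(cc$class_probs)) {
      for (s in seq_len(cc$n_slides)) {
        counts <- simulate_comet_counts(cc$class_probs[[g]], cc$n_nucleoids,
                                        seed = config$seed + 505L +
                                          100L * match(g, names(cc$class_probs)) + s)
        slides[[length(slides) + 1L]] <- data.frame(
          group = g, slide = paste0(g, "_s", s), t(counts),
          au = comet_score(counts), stringsAsFactors = FALSE)
      }
    }
    scores <- do.call(rbind, slides)
    cmps <- lapply(cc$compare, function(pair) {
      res <- compare_damage(scores$au[scores$group == pair[1]],
                            scores$au[scores$group == pair[2]])
      data.frame(group_a = pair[1], group_b = pair[2],
                 mean_a = res$mean_a, mean_b = res$mean_b,
                 t = res$t, p_value = res$p_value, stars = res$stars,
                 stringsAsFactors = FALSE)
    })
    list(scores = scores, comparisons = do.call(rbind, cmps))
  })
  write_results_table(comet$scores, file.path(out_dir, "comet_scores.csv"))
  write_results_table(comet$comparisons,
                      file.path(out_dir, "comet_comparisons.csv"))

  ## ---- qPCR ----
  qpcr <- run_stage("qpcr", {
    qc <- config$qpcr
    genes <- rownames(config$gene_effects)
    curves <- list()
    k <- 0L
    for (gene in c(genes, qc$references)) {
      for (cond in qc$conditions) {
        shift <- if (gene %in% genes) config$gene_effects[gene, cond] else 0
        for (r in seq_len(qc$n_replicates)) {
          k <- k + 1L
          curve <- simulate_qpcr_curve(
            E_true = qc$E_true, F0 = qc$F0_base * 2^shift,
            n_cycles = qc$n_cycles, noise_sd = qc$noise_sd,
            plateau = qc$plateau, seed = config$seed + 606L + k)
          curves[[k]] <- data.frame(
            reaction = sprintf("rx%03d", k), gene = gene,
            sample = paste0(cond, "_r", r), condition = cond,
            curve, stringsAsFactors = FALSE)
        }
      }
    }
    curves <- do.call(rbind, curves)
    fits <- fit_qpcr_reactions(curves)
    rel <- relative_expression(fits, targets = genes,
                               references = qc$references,
                               transitions = qc$transitions)
    list(fits = fits, relative = rel)
  })
  write_results_table(qpcr$fits, file.path(out_dir, "qpcr_quality.csv"))
  write_results_table(qpcr$relative,
                      file.path(out_dir, "qpcr_relative_expression.csv"))

  ## ---- integrate ----
  correlation <- run_stage("correlate", {
    genes <- rownames(config$gene_effects)
    prot_rows <- list()
    for (tr in config$qpcr$transitions) {
      label <- paste0(tr[1], "_vs_", tr[2])
      st <- comparisons[[label]]
      if (is.null(st)) {
        st <- run_comparison(table, tr[1], tr[2],
                             min_peptides = th$min_peptides,
                             max_missing = th$max_missing,
                             alpha = th$alpha, lfc_threshold = th$lfc)
      }
      for (gene in genes) {
        pid <- design$gene_protein[[gene]]
        row <- st$stats[st$stats$protein_id == pid, , drop = FALSE]
        prot_rows[[length(prot_rows) + 1L]] <- data.frame(
          gene = gene, first = tr[1], second = tr[2],
          log2_fc = if (nrow(row)) row$log2_fc else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    protein_fc <- do.call(rbind, prot_rows)
    transcript_fc <- qpcr$relative[, c("gene", "first", "second", "log2_fc")]
    correlate_layers(transcript_fc, protein_fc)
  })
  write_results_table(correlation$pairs,
                      file.path(out_dir, "layer_fold_changes.csv"))

  summary <- list(
    seed = config$seed,
    comparisons = summary_df,
    germination = list(
      reference = germ$reference, treated = germ$treated,
      percent_change = stats::setNames(
        as.list(germ$comparison$percent_change), germ$comparison$index)),
    comet_group_means = stats::setNames(
      as.list(tapply(comet$scores$au, comet$scores$group, mean)[
        names(config$comet$class_probs)]),
      names(config$comet$class_probs)),
    qpcr_mean_efficiency = mean(qpcr$fits$E),
    correlation = list(r = correlation$pearson$r,
                       p_value = correlation$pearson$p_value,
                       n_pairs = correlation$pearson$n,
                       n_dropped = correlation$pearson$n_dropped,
                       mann_whitney_U = correlation$mann_whitney$U,
                       mann_whitney_p = correlation$mann_whitney$p_value))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)

  log_lines <- c(log_lines,
                 sprintf("proteins simulated: %d", config$proteome$n_proteins),
                 sprintf("comparisons run: %d", length(config$comparisons)),
                 sprintf("gsea permutations: %d", config$gsea$n_perm),
                 sprintf("qpcr reactions fitted: %d", nrow(qpcr$fits)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(comparisons = comparisons, gsea = gsea_df, ora = ora,
                 germination = germ, comet = comet, qpcr = qpcr,
                 correlation = correlation, summary = summary,
                 out_dir = out_dir))
}
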