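# Container for protein-group intensity data: a protein x sample matrix of
# non-negative raw intensities (0 = not quantified), per-protein peptide
# counts and a sample -> condition assignment.

#' Construct a protein intensity table
#'
#' The central container of the proteomics side of the pipeline: raw
#' (linear-scale) protein-group intensities with zeros encoding missing
#' quantifications, razor+unique peptide counts per protein group, and the
#' experimental condition of every sample.
#'
#' @param intensities Numeric matrix, proteins in rows (rownames = protein
#'   IDs), samples in columns (colnames = sample labels). All values must be
#'   non-negative; 0 means "not quantified in this sample".
#' @param peptide_counts Integer vector, one count (>= 1) per protein, named
#'   by protein ID or in row order.
#' @param condition_of Character vector mapping each sample to its condition
#'   label, named by sample or in column order.
#' @return An object of class `intensity_table`.
#' @export
intensity_table <- function(intensities, peptide_counts, condition_of) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    fail("`intensities` must be a numeric matrix")
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    fail("`intensities` needs protein IDs as rownames and sample labels as colnames")
  if (anyDuplicated(rownames(intensities)))
    fail("duplicate protein IDs: %s",
         paste(unique(rownames(intensities)[duplicated(rownames(intensities))]),
               collapse = ", "))
  if (anyNA(intensities) || any(intensities < 0))
    fail("intensities must be non-negative and non-missing (use 0 for absent)")

  if (!is.null(names(peptide_counts))) {
    missing_ids <- setdiff(rownames(intensities), names(peptide_counts))
    if (length(missing_ids))
      fail("peptide counts missing for: %s", paste(missing_ids, collapse = ", "))
    peptide_counts <- peptide_counts[rownames(intensities)]
  } else if (length(peptide_counts) != nrow(intensities)) {
    fail("`peptide_counts` length must equal the number of proteins")
  }
  peptide_counts <- as.integer(peptide_counts)
  if (anyNA(peptide_counts) || any(peptide_counts < 1))
    fail("peptide counts must be integers >= 1")
  names(peptide_counts) <- rownames(intensities)

  if (!is.null(names(condition_of))) {
    missing_s <- setdiff(colnames(intensities), names(condition_of))
    if (length(missing_s))
      fail("condition missing for samples: %s", paste(missing_s, collapse = ", "))
    condition_of <- condition_of[colnames(intensities)]
  } else if (length(condition_of) != ncol(intensities)) {
    fail("`condition_of` length must equal the number of samples")
  }
  condition_of <- as.character(condition_of)
  if (anyNA(condition_of)) fail("every sample needs a condition label")
  names(condition_of) <- colnames(intensities)

  structure(
    list(intensities = intensities,
         peptide_counts = peptide_counts,
         condition_of = condition_of),
    class = "intensity_table"
  )
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table: %d proteins x %d samples\n",
              nrow(x$intensities), ncol(x$intensities)))
  tab <- table(x$condition_of)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat(sprintf("missing entries: %d (%.1f%%)\n",
              sum(x$intensities == 0),
              100 * mean(x$intensities == 0)))
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$intensities)

# Subset an intensity table to the samples of the given conditions.
subset_conditions <- function(table, conditions) {
  keep <- names(table$condition_of)[table$condition_of %in% conditions]
  if (!length(keep)) fail("no samples for conditions: %s",
                          paste(conditions, collapse = ", "))
  intensity_table(table$intensities[, keep, drop = FALSE],
                  table$peptide_counts,
                  table$condition_of[keep])
}
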