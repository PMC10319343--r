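# Readers and writers for the tabular formats the pipeline touches:
# proteinGroups-style TSV (MaxQuant dialect), GMT gene-set files, and CSV
# result tables. Only three proteinGroups columns are interpreted (ID,
# peptide count, intensities matched by prefix); everything else is
# ignored, which keeps the reader tolerant across search-engine versions.

#' Read a proteinGroups-style protein intensity table
#'
#' Parses a tab-separated protein-group quantification table (MaxQuant
#' `proteinGroups.txt` dialect). Intensity columns are matched by a column
#' name prefix; the remainder of each matching name becomes the sample
#' label. Contaminant (`CON__`) and decoy (`REV__`) rows are dropped.
#' Zeros, empty cells and `NaN` literals in intensity columns all normalize
#' to 0 (missing), mirroring how the search software encodes absent
#' quantifications. Negative intensities are rejected.
#'
#' @param path Path to the TSV file.
#' @param design Optional data.frame with columns `sample`, `condition`
#'   mapping sample labels to condition labels. If omitted, each sample is
#'   its own condition.
#' @param intensity_prefix Column-name prefix of per-sample intensity
#'   columns (default `"Intensity "`; the bare total `"Intensity"` column is
#'   never matched).
#' @param id_column Name of the protein ID column (default
#'   `"Protein IDs"`).
#' @param peptides_column Name of the peptide-count column (default
#'   `"Peptides"`; which peptide count to use is search-output dependent, so
#'   it is configurable).
#' @return An [intensity_table()].
#' @export
read_protein_groups <- function(path, design = NULL,
                                intensity_prefix = "Intensity ",
                                id_column = "Protein IDs",
                                peptides_column = "Peptides") {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(id_column, peptides_column), names(raw))
  if (length(missing_cols))
    fail("missing required columns: %s", paste(missing_cols, collapse = ", "))
  int_cols <- names(raw)[startsWith(names(raw), intensity_prefix) &
                           nchar(names(raw)) > nchar(intensity_prefix)]
  if (!length(int_cols))
    fail("no intensity columns matching prefix '%s'", intensity_prefix)

  ids <- as.character(raw[[id_column]])
  keep <- !grepl("^(CON__|REV__)", ids)
  raw <- raw[keep, , drop = FALSE]
  ids <- ids[keep]
  if (anyDuplicated(ids))
    fail("duplicate protein IDs in %s: %s", path,
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  x <- as.matrix(raw[, int_cols, drop = FALSE])
  suppressWarnings(storage.mode(x) <- "double")
  x[is.na(x) | is.nan(x)] <- 0
  if (any(x < 0)) fail("negative intensities in %s are not allowed", path)
  samples <- substring(int_cols, nchar(intensity_prefix) + 1L)
  dimnames(x) <- list(ids, samples)

  condition_of <- if (is.null(design)) {
    stats::setNames(samples, samples)
  } else {
    if (!all(c("sample", "condition") %in% names(design)))
      fail("`design` needs columns `sample` and `condition`")
    stats::setNames(as.character(design$condition), design$sample)[samples]
  }
  intensity_table(x, stats::setNames(raw[[peptides_column]], ids), condition_of)
}

#' Write an intensity table in the proteinGroups dialect
#'
#' Emits the same dialect [read_protein_groups()] consumes, so generated
#' fixtures round-trip.
#'
#' @param table An [intensity_table()].
#' @param path Output TSV path.
#' @inheritParams read_protein_groups
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(table, path,
                                  intensity_prefix = "Intensity ",
                                  id_column = "Protein IDs",
                                  peptides_column = "Peptides") {
  stopifnot(inherits(table, "intensity_table"))
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    id = rownames(table$intensities),
                    pep = unname(table$peptide_counts))
  names(out) <- c(id_column, peptides_column)
  ints <- as.data.frame(table$intensities, check.names = FALSE)
  names(ints) <- paste0(intensity_prefix, names(ints))
  utils::write.table(cbind(out, ints), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A named list of class `gene_set_collection`; each element is a
#'   character vector of member IDs with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty gene-set file: ", path)
    return(structure(list(), class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    fail("GMT line %d has fewer than 3 tab-separated fields", bad[1])
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_))
    fail("duplicate gene-set names: %s",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  sets <- lapply(fields, function(f) {
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) fail("gene set '%s' has no members", f[[1]])
    attr(members, "description") <- f[[2]]
    members
  })
  structure(stats::setNames(sets, names_), class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of member-ID character vectors (descriptions taken
#'   from each element's `description` attribute, if present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a results table as CSV
#'
#' CSV with header and stable column order; missing values are written as
#' empty fields and logical flags as lowercase `true`/`false` literals.
#'
#' @param records A data.frame of results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.logical(out[[j]])) out[[j]] <- tolower(as.character(out[[j]]))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' `true`/`false` columns are restored to logical; empty fields to `NA`.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_results_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.character(v) && all(v %in% c("true", "false", NA)))
      out[[j]] <- v == "true"
  }
  out
}
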