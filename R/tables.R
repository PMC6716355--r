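#' Unique-sequence count table
#'
#' The central container of the pre-clustering pipeline: a sample x sequence
#' matrix of dereplicated read counts, the sequence strings themselves, and
#' the set of sample ids that act as negative controls during
#' decontamination.
#'
#' @param counts integer matrix, rows = samples, columns = unique sequences.
#'   Both dimensions must be named.
#' @param sequences named character vector mapping sequence id to its DNA
#'   string; names must match `colnames(counts)`.
#' @param control_ids character vector of sample ids flagged as negative
#'   controls; must be a subset of `rownames(counts)`.
#' @return An object of class `uniqueseq_table` with components `counts`,
#'   `sequences` and `control_ids`.
#' @export
uniqueseq_table <- function(counts, sequences, control_ids = character()) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have sample row names and sequence column names")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!setequal(names(sequences), colnames(counts)))
    stop("sequence ids must match count-table columns")
  sequences <- sequences[colnames(counts)]
  if (anyDuplicated(sequences))
    stop("duplicate sequence strings: dereplicate first")
  if (!all(control_ids %in% rownames(counts)))
    stop("control_ids must be a subset of sample ids")
  structure(
    list(counts = counts, sequences = sequences,
         control_ids = as.character(control_ids)),
    class = "uniqueseq_table")
}

#' Per-sample library sizes of a unique-sequence table
#' @param table a `uniqueseq_table`
#' @return named numeric vector of per-sample read totals
#' @export
library_sizes <- function(table) rowSums(table$counts)

#' @export
print.uniqueseq_table <- function(x, ...) {
  cat(sprintf("uniqueseq_table: %d samples x %d unique sequences (%d controls)\n",
              nrow(x$counts), ncol(x$counts), length(x$control_ids)))
  cat(sprintf("  total reads: %s\n", format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' OTU table with representative sequences
#'
#' @param counts integer matrix, rows = samples, columns = OTUs (named).
#' @param representatives named character vector of representative DNA
#'   strings, one per OTU.
#' @param members named list mapping OTU id to member sequence ids.
#' @return An object of class `otu_tab`.
#' @export
otu_tab <- function(counts, representatives, members = NULL) {
  counts <- as.matrix(counts)
  if (!setequal(names(representatives), colnames(counts)))
    stop("representative ids must match count-table columns")
  if (is.null(members))
    members <- stats::setNames(as.list(colnames(counts)), colnames(counts))
  structure(
    list(counts = counts,
         representatives = representatives[colnames(counts)],
         members = members[colnames(counts)]),
    class = "otu_tab")
}

#' @export
print.otu_tab <- function(x, ...) {
  cat(sprintf("otu_tab: %d samples x %d OTUs\n", nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Write a unique-sequence table to TSV
#'
#' Rows are sequences (id + DNA string), columns are samples, matching the
#' on-disk orientation used for dereplicated count tables.
#'
#' @param table a `uniqueseq_table`
#' @param path output file path
#' @export
write_seqtab_tsv <- function(table, path) {
  df <- data.frame(sequence_id = colnames(table$counts),
                   sequence = unname(table$sequences),
                   t(table$counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a unique-sequence table from TSV
#'
#' @param path TSV written by [write_seqtab_tsv()]
#' @param control_ids sample ids to flag as negative controls
#' @return a `uniqueseq_table`
#' @export
read_seqtab_tsv <- function(path, control_ids = character()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  counts <- t(as.matrix(df[, -(1:2), drop = FALSE]))
  colnames(counts) <- df$sequence_id
  uniqueseq_table(counts, stats::setNames(df$sequence, df$sequence_id),
                  control_ids)
}

#' Write sample metadata to TSV
#' @param design data.frame as returned by [enumerate_design()]
#' @param path output file path
#' @export
write_metadata_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#' @param path TSV with columns sample_id, stage, compartment, treatment,
#'   is_negative_control
#' @return data.frame
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$is_negative_control <- as.logical(df$is_negative_control)
  df
}

#' Write an OTU table to TSV (plus optional representatives FASTA)
#' @param otu an `otu_tab`
#' @param path TSV output path
#' @param fasta optional path for a representatives FASTA
#' @export
write_otutab_tsv <- function(otu, path, fasta = NULL) {
  df <- data.frame(otu_id = colnames(otu$counts),
                   representative = unname(otu$representatives),
                   t(otu$counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) {
    set <- Biostrings::DNAStringSet(otu$representatives)
    Biostrings::writeXStringSet(set, fasta)
  }
  invisible(path)
}
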