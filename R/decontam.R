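#' Parameters of the iterative negative-control decontamination
#'
#' @param control_ratio a unique sequence survives step 1 only if some
#'   experimental library carries it at at least `control_ratio` times its
#'   maximum relative abundance in any negative control (default 10)
#' @param min_relabund step-2 floor: a sequence must account for at least
#'   this fraction of at least one experimental library (default 0.001,
#'   i.e. 0.1%)
#' @param max_filtered_fraction step-3 cap: samples whose filtered reads
#'   exceed this fraction of their starting reads are discarded
#'   (default 0.75, so samples retaining less than 25% are removed; exactly
#'   25% retained is kept)
#' @return list of class `decontam_params`
#' @export
decontam_params <- function(control_ratio = 10, min_relabund = 0.001,
                            max_filtered_fraction = 0.75) {
  stopifnot(control_ratio > 0,
            min_relabund > 0, min_relabund < 1,
            max_filtered_fraction > 0, max_filtered_fraction < 1)
  structure(list(control_ratio = control_ratio,
                 min_relabund = min_relabund,
                 max_filtered_fraction = max_filtered_fraction),
            class = "decontam_params")
}

#' Relative abundances against current library sizes
#'
#' @param table a [uniqueseq_table()]
#' @return matrix of per-sample fractions; every row sums to 1
#' @export
relative_abundance <- function(table) {
  sizes <- library_sizes(table)
  if (any(sizes == 0))
    stop("zero-size library: ",
         paste(names(sizes)[sizes == 0], collapse = ", "))
  sweep(table$counts, 1, sizes, "/")
}

# relative abundances tolerating empty samples (rows of zeros stay zero)
relabund0 <- function(counts) {
  sizes <- rowSums(counts)
  sizes[sizes == 0] <- 1
  sweep(counts, 1, sizes, "/")
}

#' Step 1: the 10x negative-control abundance rule
#'
#' A unique sequence is kept iff some experimental library carries it at a
#' relative abundance at least `control_ratio` times its maximum relative
#' abundance over the negative controls. Sequences absent from every
#' control are kept iff present in any experimental library.
#'
#' @param table a [uniqueseq_table()] with at least one control and one
#'   experimental sample
#' @param params a [decontam_params()]
#' @return character vector of kept sequence ids
#' @export
step1_control_ratio <- function(table, params = decontam_params()) {
  is_ctl <- rownames(table$counts) %in% table$control_ids
  if (!any(is_ctl)) stop("no negative-control samples present")
  if (all(is_ctl)) stop("no experimental samples present")
  rel <- relabund0(table$counts)
  max_ctl <- apply(rel[is_ctl, , drop = FALSE], 2, max)
  rel_exp <- rel[!is_ctl, , drop = FALSE]
  best_exp <- apply(rel_exp, 2, max)
  keep <- best_exp > 0 & best_exp >= params$control_ratio * max_ctl
  colnames(table$counts)[keep]
}

#' Step 2: the 0.1% minimum-abundance floor
#'
#' A unique sequence is kept iff it accounts for at least `min_relabund` of
#' at least one experimental library (controls do not count as experimental
#' libraries here).
#'
#' @inheritParams step1_control_ratio
#' @return character vector of kept sequence ids
#' @export
step2_min_abundance <- function(table, params = decontam_params()) {
  is_ctl <- rownames(table$counts) %in% table$control_ids
  rel_exp <- relabund0(table$counts[!is_ctl, , drop = FALSE])
  if (nrow(rel_exp) == 0 || ncol(rel_exp) == 0) return(character(0))
  keep <- apply(rel_exp, 2, max) >= params$min_relabund
  colnames(table$counts)[keep]
}

#' Step 3: discard over-filtered samples
#'
#' A sample is kept iff its current reads are at least
#' `1 - max_filtered_fraction` of its starting (post-QC,
#' pre-decontamination) reads. With the default 0.75 this keeps samples
#' retaining at least 25%; a sample at exactly 25% is kept, since only
#' strictly more than 75% filtered is "too highly contaminated".
#'
#' @param table a [uniqueseq_table()]
#' @param starting_sizes named numeric vector of the original library sizes
#' @param params a [decontam_params()]
#' @return character vector of kept sample ids
#' @export
step3_sample_retention <- function(table, starting_sizes,
                                   params = decontam_params()) {
  samples <- rownames(table$counts)
  if (!all(samples %in% names(starting_sizes)))
    stop("starting_sizes missing for: ",
         paste(setdiff(samples, names(starting_sizes)), collapse = ", "))
  retained <- rowSums(table$counts) / starting_sizes[samples]
  samples[retained >= 1 - params$max_filtered_fraction]
}

drop_cols <- function(table, keep_ids) {
  uniqueseq_table(table$counts[, keep_ids, drop = FALSE],
                  table$sequences[keep_ids],
                  table$control_ids)
}

drop_rows <- function(table, keep_samples) {
  uniqueseq_table(table$counts[keep_samples, , drop = FALSE],
                  table$sequences,
                  intersect(table$control_ids, keep_samples))
}

#' Iterative four-step negative-control decontamination
#'
#' Applies, in order: (1) the 10x control-abundance rule, (2) the 0.1%
#' minimum-abundance floor, (3) discarding of samples that lost more than
#' 75% of their starting reads — then repeats the three steps on the
#' reduced table (step 4) until a full pass removes nothing. Relative
#' abundances are always recomputed from the current (post-removal) library
#' sizes, while step 3 compares against the original starting sizes.
#' Control samples never count as experimental libraries in steps 1-2 but
#' are themselves subject to step-3 discard; once discarded they stop
#' contributing control maxima. If every control is discarded, step 1
#' reduces to keeping sequences present in any experimental library.
#'
#' @param table a [uniqueseq_table()] with at least one control sample
#' @param params a [decontam_params()]
#' @return list with `table` (the filtered [uniqueseq_table()]) and
#'   `report` (class `decontam_report`): per-iteration removals, read
#'   accounting, final retained samples and per-sample retained fractions.
#'   If every experimental sample is discarded this is reported, not fatal.
#' @export
run_decontam <- function(table, params = decontam_params()) {
  if (length(table$control_ids) == 0)
    # tolerated (the 10x rule reduces to presence) so that re-running the
    # procedure on its own control-free output is a no-op
    message("no negative-control samples: step 1 reduces to presence filtering")
  starting_sizes <- library_sizes(table)
  iterations <- list()
  repeat {
    reads_before <- sum(table$counts)
    seqs_before <- colnames(table$counts)
    samples_before <- rownames(table$counts)

    keep1 <- if (length(table$control_ids) == 0) {
      # every control already discarded: the rule reduces to presence
      colnames(table$counts)[colSums(table$counts) > 0]
    } else {
      step1_control_ratio(table, params)
    }
    removed1 <- setdiff(seqs_before, keep1)
    table <- drop_cols(table, keep1)

    keep2 <- step2_min_abundance(table, params)
    removed2 <- setdiff(colnames(table$counts), keep2)
    table <- drop_cols(table, keep2)

    keep3 <- step3_sample_retention(table, starting_sizes, params)
    removed_samples <- setdiff(samples_before, keep3)
    table <- drop_rows(table, keep3)

    iterations[[length(iterations) + 1L]] <- list(
      removed_sequences_step1 = removed1,
      removed_sequences_step2 = removed2,
      removed_samples = removed_samples,
      reads_before = reads_before,
      reads_after = sum(table$counts))

    if (length(removed1) == 0 && length(removed2) == 0 &&
        length(removed_samples) == 0) break
    if (nrow(table$counts) == 0 || ncol(table$counts) == 0) break
    if (!any(!(rownames(table$counts) %in% table$control_ids))) break
  }
  is_ctl <- rownames(table$counts) %in% table$control_ids
  retained_frac <- rowSums(table$counts) /
    starting_sizes[rownames(table$counts)]
  report <- structure(list(
    iterations = iterations,
    n_iterations = length(iterations),
    starting_sizes = starting_sizes,
    final_retained_samples = rownames(table$counts),
    per_sample_retained_fraction = retained_frac,
    total_reads_start = sum(starting_sizes),
    total_reads_final = sum(table$counts),
    retained_read_pct = 100 * sum(table$counts) / sum(starting_sizes),
    all_experimental_removed = !any(!is_ctl)),
    class = "decontam_report")
  if (report$all_experimental_removed)
    warning("all experimental samples were discarded during decontamination")
  list(table = table, report = report)
}

#' @export
print.decontam_report <- function(x, ...) {
  cat(sprintf(
    "decontam_report: %d iteration(s); %d samples retained; %s of %s reads (%.2f%%)\n",
    x$n_iterations, length(x$final_retained_samples),
    format(x$total_reads_final, big.mark = ","),
    format(x$total_reads_start, big.mark = ","),
    x$retained_read_pct))
  for (i in seq_along(x$iterations)) {
    it <- x$iterations[[i]]
    cat(sprintf(
      "  iter %d: -%d seqs (step1), -%d seqs (step2), -%d samples (step3); reads %s -> %s\n",
      i, length(it$removed_sequences_step1),
      length(it$removed_sequences_step2), length(it$removed_samples),
      format(it$reads_before, big.mark = ","),
      format(it$reads_after, big.mark = ",")))
  }
  invisible(x)
}

#' Serialize a decontamination report to JSON
#' @param report a `decontam_report`
#' @param path output path
#' @export
write_decontam_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
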