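#' Read a FASTQ file (phred+33)
#'
#' @param path FASTQ path
#' @return list with `ids`, `seqs` (character) and `quals` (list of integer
#'   phred scores)
#' @export
read_fastq <- function(path) {
  # withCallingHandlers: the reader warns about dropped metadata columns on
  # plain 4-line FASTQ, which carries none worth keeping
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  quals <- as(Biostrings::quality(x), "IntegerList")
  list(ids = sub(" .*", "", names(x)),
       seqs = unname(as.character(x)),
       quals = unname(as.list(quals)))
}

#' Merge one read pair by best overlap
#'
#' Scans every candidate overlap of at least `min_overlap` bases between the
#' 3' end of the forward mate and the reverse complement of the reverse
#' mate, and keeps the overlap with the most matching bases among those with
#' at least `min_identity` identity (ties resolved towards the longer
#' overlap). Within the overlap, mismatching columns take the base with the
#' higher phred score; overlap quality is the columnwise maximum.
#'
#' @param seq1,seq2 mate sequences (ACGTN)
#' @param qual1,qual2 integer phred vectors, same lengths as the mates
#' @param min_overlap minimum acceptable overlap in bases (default 10)
#' @param min_identity minimum overlap identity for acceptance (default 0.9)
#' @return list(seq, qual) for the merged read, or NULL when no acceptable
#'   overlap exists (rejection)
#' @export
merge_pair <- function(seq1, qual1, seq2, qual2,
                       min_overlap = 10, min_identity = 0.9) {
  stopifnot(nchar(seq1) > 0, nchar(seq2) > 0,
            nchar(seq1) == length(qual1), nchar(seq2) == length(qual2))
  c1 <- strsplit(seq1, "")[[1]]
  c2 <- strsplit(revcomp(seq2), "")[[1]]
  q2 <- rev(qual2)
  l1 <- length(c1); l2 <- length(c2)
  if (min(l1, l2) < min_overlap) return(NULL)
  best_ov <- 0L; best_matches <- -1L
  for (ov in seq(min(l1, l2), min_overlap)) {
    m <- sum(c1[(l1 - ov + 1):l1] == c2[1:ov])
    if (m / ov >= min_identity && m > best_matches) {
      best_matches <- m; best_ov <- ov
    }
  }
  if (best_ov == 0L) return(NULL)
  ov <- best_ov
  i1 <- (l1 - ov + 1):l1
  i2 <- 1:ov
  take2 <- c1[i1] != c2[i2] & q2[i2] > qual1[i1]
  cons <- ifelse(take2, c2[i2], c1[i1])
  consq <- pmax(qual1[i1], q2[i2])
  list(seq = paste(c(c1[seq_len(l1 - ov)], cons, c2[-seq_len(ov)]),
                   collapse = ""),
       qual = c(qual1[seq_len(l1 - ov)], consq, q2[-seq_len(ov)]))
}

#' Quality filter for merged reads
#'
#' A read fails when it is shorter than `min_length` bases, when its mean
#' phred score is less than or equal to `qual_cutoff`, or when it contains
#' any ambiguous base call (N). The mean-quality rule is applied verbatim as
#' an inclusive cutoff.
#'
#' @param seq DNA string
#' @param qual integer phred vector, same length as `seq`
#' @param min_length minimum length in bases (default 200)
#' @param qual_cutoff reads with mean quality <= this fail (default 30)
#' @return list(pass = logical, reason = NA or one of
#'   "length"/"quality"/"ambiguous")
#' @export
qc_filter <- function(seq, qual, min_length = 200, qual_cutoff = 30) {
  stopifnot(nchar(seq) == length(qual))
  if (nchar(seq) < min_length)
    return(list(pass = FALSE, reason = "length"))
  if (mean(qual) <= qual_cutoff)
    return(list(pass = FALSE, reason = "quality"))
  if (grepl("N", seq, fixed = TRUE))
    return(list(pass = FALSE, reason = "ambiguous"))
  list(pass = TRUE, reason = NA_character_)
}

#' Demultiplex merged reads by exact barcode and primer match
#'
#' A read is assigned to a sample iff its leading 6 bases exactly match that
#' sample's barcode and the forward primer follows immediately and exactly;
#' barcode and primer are trimmed from the retained sequence. Everything
#' else is discarded. Barcodes are read on the forward (leading) end only,
#' which is treated as canonical.
#'
#' @param seqs character vector of merged sequences
#' @param barcode_map named character vector sample_id -> 6-bp barcode
#' @param fwd_primer primer expected immediately after the barcode
#' @return list(assigned = named list of trimmed sequence vectors per
#'   sample, sample_of = per-read sample id or NA, n_discarded)
#' @export
demultiplex <- function(seqs, barcode_map,
                        fwd_primer = "ACTCCTACGGGAGGCAGCAG") {
  if (any(nchar(barcode_map) != 6)) stop("barcodes must be exactly 6 bp")
  if (anyDuplicated(barcode_map)) stop("duplicate barcodes in map")
  np <- nchar(fwd_primer)
  bc <- substr(seqs, 1, 6)
  pr <- substr(seqs, 7, 6 + np)
  sample_of <- names(barcode_map)[match(bc, barcode_map)]
  sample_of[!is.na(sample_of) & pr != fwd_primer] <- NA
  trimmed <- substring(seqs, 7 + np)
  assigned <- lapply(stats::setNames(nm = names(barcode_map)), function(s)
    trimmed[!is.na(sample_of) & sample_of == s])
  list(assigned = assigned, sample_of = sample_of,
       n_discarded = sum(is.na(sample_of)))
}

#' Dereplicate per-sample sequences into a unique-sequence table
#'
#' Identical full-length strings collapse to one table column; per-sample
#' counts are recorded. Columns are ordered by decreasing total count, ties
#' broken by the sequence string, so the table is deterministic regardless
#' of read order.
#'
#' @param sample_seqs named list: sample id -> character vector of sequences
#' @param control_ids sample ids to flag as negative controls
#' @return a [uniqueseq_table()]
#' @export
dereplicate <- function(sample_seqs, control_ids = character()) {
  all_seq <- sort(unique(unlist(sample_seqs, use.names = FALSE)))
  if (length(all_seq) == 0) {
    empty <- matrix(0L, length(sample_seqs), 0,
                    dimnames = list(names(sample_seqs), NULL))
    return(uniqueseq_table(empty, stats::setNames(character(0), character(0)),
                           control_ids))
  }
  counts <- vapply(sample_seqs, function(v)
    tabulate(match(v, all_seq), nbins = length(all_seq)),
    integer(length(all_seq)))
  counts <- t(matrix(counts, nrow = length(all_seq),
                     dimnames = list(NULL, names(sample_seqs))))
  ord <- order(-colSums(counts), all_seq)
  counts <- counts[, ord, drop = FALSE]
  all_seq <- all_seq[ord]
  ids <- sprintf("seq_%06d", seq_along(all_seq))
  colnames(counts) <- ids
  uniqueseq_table(counts, stats::setNames(all_seq, ids), control_ids)
}

#' Run the full read-processing pipeline on paired FASTQ
#'
#' merge -> quality filter -> demultiplex -> dereplicate, with read-count
#' accounting at every stage (assigned + discarded always equals the input
#' read count).
#'
#' @param r1,r2 FASTQ paths for the forward and reverse mates
#' @param barcode_map named character vector sample_id -> 6-bp barcode
#' @param control_ids sample ids to flag as negative controls
#' @param fwd_primer forward primer following the barcode
#' @param min_overlap,min_identity merge parameters (see [merge_pair()])
#' @param min_length,qual_cutoff filter parameters (see [qc_filter()])
#' @return list(table = [uniqueseq_table()], log = data.frame(read_id,
#'   fate), accounting = named counts per stage)
#' @export
process_fastq_pairs <- function(r1, r2, barcode_map,
                                control_ids = character(),
                                fwd_primer = "ACTCCTACGGGAGGCAGCAG",
                                min_overlap = 10, min_identity = 0.9,
                                min_length = 200, qual_cutoff = 30) {
  f1 <- read_fastq(r1)
  f2 <- read_fastq(r2)
  n <- length(f1$seqs)
  stopifnot(length(f2$seqs) == n)
  fate <- character(n)
  merged <- character(n)
  for (i in seq_len(n)) {
    m <- merge_pair(f1$seqs[i], f1$quals[[i]], f2$seqs[i], f2$quals[[i]],
                    min_overlap = min_overlap, min_identity = min_identity)
    if (is.null(m)) { fate[i] <- "merge_failed"; next }
    qc <- qc_filter(m$seq, m$qual, min_length = min_length,
                    qual_cutoff = qual_cutoff)
    if (!qc$pass) { fate[i] <- paste0("qc_", qc$reason); next }
    merged[i] <- m$seq
    fate[i] <- "merged"
  }
  ok <- fate == "merged"
  dmx <- demultiplex(merged[ok], barcode_map, fwd_primer)
  fate[ok][is.na(dmx$sample_of)] <- "unassigned"
  fate[ok][!is.na(dmx$sample_of)] <- "assigned"
  table <- dereplicate(dmx$assigned, control_ids)
  acct <- c(input = n,
            merge_failed = sum(fate == "merge_failed"),
            qc_failed = sum(startsWith(fate, "qc_")),
            unassigned = sum(fate == "unassigned"),
            assigned = sum(fate == "assigned"))
  list(table = table,
       log = data.frame(read_id = f1$ids, fate = fate,
                        stringsAsFactors = FALSE),
       accounting = acct)
}
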