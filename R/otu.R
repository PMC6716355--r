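#' Pairwise global-alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1, linear gap
#' penalty -2; identity is the fraction of matching columns over all
#' alignment columns after trimming terminal-gap columns. Symmetric in its
#' arguments.
#'
#' @param a,b non-empty DNA strings
#' @return identity fraction in \[0, 1\]
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  identity_to_centroids(a, b)
}

# vectorized identity of one query against many references; when a
# threshold is given, pairs whose cheap upper bound (matches over
# match+mismatch columns: the denominator can only grow with gaps) cannot
# reach it skip the costly aligned-string extraction and report the bound
identity_to_centroids <- function(query, refs, threshold = NULL) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(rep(query, length(refs))),
    Biostrings::DNAStringSet(refs),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  ub <- ifelse(nm + nmm == 0, 0, nm / (nm + nmm))
  exact_idx <- if (is.null(threshold)) seq_along(refs) else
    which(ub >= threshold)
  out <- ub
  for (i in exact_idx) {
    p <- strsplit(as.character(Biostrings::alignedPattern(aln[i])), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln[i])), "")[[1]]
    gap <- p == "-" | s == "-"
    inner <- which(!gap)          # trim terminal gap columns only
    out[i] <- if (length(inner) == 0) 0 else {
      span <- inner[1]:inner[length(inner)]
      sum(p[span] == s[span] & !gap[span]) / length(span)
    }
  }
  out
}

#' Greedy de novo OTU clustering at a fixed identity threshold
#'
#' Abundance-sorted greedy centroid clustering: unique sequences are
#' processed in decreasing total-count order (ties broken by the sequence
#' string), each joining the first existing centroid it matches at
#' `threshold` identity or better, otherwise founding a new OTU with itself
#' as representative. Deterministic and invariant to input column order.
#'
#' @param table a [uniqueseq_table()]
#' @param threshold identity threshold in (0, 1\] (default 0.97)
#' @return an [otu_tab()]
#' @export
greedy_cluster <- function(table, threshold = 0.97) {
  stopifnot(threshold > 0, threshold <= 1)
  totals <- colSums(table$counts)
  ord <- order(-totals, table$sequences)
  ids <- colnames(table$counts)[ord]
  reps <- character(0)       # representative strings, in founding order
  rep_ids <- character(0)
  members <- list()
  assignment <- stats::setNames(character(length(ids)), ids)
  for (u in ids) {
    s <- table$sequences[[u]]
    hit <- NA_character_
    if (length(reps) > 0) {
      exact <- match(s, reps)
      if (!is.na(exact)) {
        hit <- rep_ids[exact]
      } else {
        idy <- identity_to_centroids(s, reps, threshold = threshold)
        k <- which(idy >= threshold)[1]
        if (!is.na(k)) hit <- rep_ids[k]
      }
    }
    if (is.na(hit)) {
      oid <- sprintf("OTU_%04d", length(reps) + 1L)
      reps <- c(reps, s)
      rep_ids <- c(rep_ids, oid)
      members[[oid]] <- character(0)
      hit <- oid
    }
    members[[hit]] <- c(members[[hit]], u)
    assignment[u] <- hit
  }
  counts <- matrix(0, nrow(table$counts), length(rep_ids),
                   dimnames = list(rownames(table$counts), rep_ids))
  for (oid in rep_ids)
    counts[, oid] <- rowSums(table$counts[, members[[oid]], drop = FALSE])
  storage.mode(counts) <- "integer"
  otu_tab(counts, stats::setNames(reps, rep_ids), members)
}

#' Rarefy an OTU table to a common depth
#'
#' Subsamples each sample's reads without replacement (hypergeometric
#' draw, via [vegan::rrarefy()]) down to `depth`. Samples with fewer than
#' `depth` reads are dropped with a warning.
#'
#' @param otu an [otu_tab()]
#' @param depth target reads per sample (e.g. 7096)
#' @param seed integer seed
#' @return an [otu_tab()] whose sample totals all equal `depth`
#' @export
rarefy_table <- function(otu, depth, seed = 1) {
  stopifnot(depth > 0)
  sizes <- rowSums(otu$counts)
  keep <- sizes >= depth
  if (!all(keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(names(sizes)[!keep], collapse = ", "))
  if (!any(keep)) stop("no sample reaches the rarefaction depth")
  counts <- otu$counts[keep, , drop = FALSE]
  # rrarefy's heuristic "smallest count" warning misfires on OTU-collapsed
  # tables; the draw itself is the plain hypergeometric we want
  rare <- withr::with_seed(seed, suppressWarnings(vegan::rrarefy(counts, depth)))
  storage.mode(rare) <- "integer"
  otu_tab(rare, otu$representatives, otu$members)
}
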