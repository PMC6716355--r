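#' Hellinger transform of an OTU table
#'
#' sqrt of per-sample relative abundances; every transformed sample row has
#' unit L2 norm. Down-weights dominant taxa ahead of distance computation.
#'
#' @param otu an [otu_tab()] or a sample x taxon count matrix
#' @return numeric matrix of the same shape
#' @export
hellinger <- function(otu) {
  counts <- if (inherits(otu, "otu_tab")) otu$counts else as.matrix(otu)
  if (any(rowSums(counts) == 0)) stop("zero-total sample")
  vegan::decostand(counts, method = "hellinger")
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(j, k) = sum |x_ij - x_ik| / sum (x_ij + x_ik) over taxa i, computed
#' between all sample pairs.
#'
#' @param mat sample x taxon non-negative matrix (e.g. Hellinger-transformed
#'   counts)
#' @return symmetric matrix with zero diagonal, entries in \[0, 1\]
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("negative entries")
  if (sum(rowSums(mat) == 0) >= 2)
    stop("dissimilarity undefined between two all-zero samples")
  as.matrix(vegan::vegdist(mat, method = "bray"))
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS (monotone regression with primary treatment of
#' ties) via [vegan::metaMDS()], taking the best of `n_starts` random
#' starts. Non-convergence is reported in the result, never an error.
#'
#' @param d square dissimilarity matrix (or `dist`)
#' @param k embedding dimension (default 2); must be < number of samples
#' @param n_starts random starts (default 20)
#' @param max_iter iteration cap per start (default 500)
#' @param seed integer seed
#' @return list(coordinates, stress, n_starts, converged)
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 500, seed = 1) {
  dd <- stats::as.dist(d)
  n <- attr(dd, "Size")
  if (k >= n) stop("k must be smaller than the number of samples")
  fit <- withr::with_seed(seed, suppressWarnings(
    vegan::metaMDS(dd, k = k, try = n_starts, trymax = n_starts,
                   maxit = max_iter, trace = 0, autotransform = FALSE,
                   wascores = FALSE)))
  list(coordinates = vegan::scores(fit, display = "sites"),
       stress = fit$stress,
       n_starts = n_starts,
       converged = isTRUE(fit$converged) || fit$converged > 0)
}

#' ANOSIM: analysis of similarities
#'
#' Rank-based permutation test of group separation on a dissimilarity
#' matrix: R = (mean between-group rank - mean within-group rank) / (M/2)
#' with M = n(n-1)/2, permutation p = (1 + #\{permuted R >= observed\}) /
#' (1 + n_perm). Backed by [vegan::anosim()].
#'
#' @param d square dissimilarity matrix (or `dist`)
#' @param groups group label per sample; >= 2 groups, each with n >= 2
#' @param n_perm number of permutations (default 999)
#' @param seed integer seed
#' @return list(R, p, n_permutations)
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs n >= 2")
  fit <- withr::with_seed(seed,
                          vegan::anosim(stats::as.dist(d), groups,
                                        permutations = n_perm))
  list(R = unname(fit$statistic), p = fit$signif, n_permutations = n_perm)
}

#' Write a dissimilarity matrix as square TSV
#' @param d square matrix
#' @param path output path
#' @export
write_dissimilarity_tsv <- function(d, path) {
  d <- as.matrix(d)
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
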