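#' Spearman rank correlation with a t-approximation p-value
#'
#' Midrank-based rho; two-sided p from the t distribution with n - 2
#' degrees of freedom. Zero-variance vectors have no defined rank
#' correlation and are an error.
#'
#' @param x,y numeric vectors of equal length, n >= 4
#' @return list(rho, p)
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 4) stop("need equal lengths with n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance vector: rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' The k most abundant OTUs
#'
#' @param otu an [otu_tab()]
#' @param k how many OTUs (default 20); if the table has fewer, all are
#'   returned with a warning
#' @return character vector of OTU ids ordered by decreasing total count,
#'   ties broken by id
#' @export
top_k_otus <- function(otu, k = 20) {
  totals <- colSums(otu$counts)
  ord <- order(-totals, colnames(otu$counts))
  if (ncol(otu$counts) < k) {
    warning("table has only ", ncol(otu$counts), " OTUs; returning all")
    k <- ncol(otu$counts)
  }
  colnames(otu$counts)[ord][seq_len(k)]
}

#' Signed Spearman co-occurrence network over the most abundant OTUs
#'
#' Scores every pair among the top `k` OTUs on per-sample relative
#' abundances and emits an edge when |rho| >= `rho_threshold` and
#' p < `alpha`. Edges are canonical (otu_a < otu_b), carry their sign, and
#' receive no multiple-testing correction unless `adjust = TRUE`
#' (Benjamini-Hochberg).
#'
#' @param otu an [otu_tab()] (typically rarefied)
#' @param k number of top OTUs (default 20)
#' @param rho_threshold absolute-correlation threshold (default 0.75)
#' @param alpha p-value threshold (default 0.05)
#' @param adjust apply BH correction across all scored pairs (default FALSE)
#' @return data.frame(otu_a, otu_b, rho, p, sign); zero rows when no pair
#'   qualifies
#' @export
build_network <- function(otu, k = 20, rho_threshold = 0.75, alpha = 0.05,
                          adjust = FALSE) {
  if (nrow(otu$counts) < 4) stop("need at least 4 samples")
  ids <- top_k_otus(otu, k)
  rel <- sweep(otu$counts[, ids, drop = FALSE], 1,
               rowSums(otu$counts), "/")
  pairs <- utils::combn(sort(ids), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- rel[, pr[1]]; b <- rel[, pr[2]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NULL)
    sc <- spearman_cor(a, b)
    data.frame(otu_a = pr[1], otu_b = pr[2], rho = sc$rho, p = sc$p,
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  if (is.null(edges))
    return(data.frame(otu_a = character(0), otu_b = character(0),
                      rho = numeric(0), p = numeric(0),
                      sign = character(0), stringsAsFactors = FALSE))
  if (adjust) edges$p <- stats::p.adjust(edges$p, method = "BH")
  edges <- edges[abs(edges$rho) >= rho_threshold & edges$p < alpha, ,
                 drop = FALSE]
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  rownames(edges) <- NULL
  edges
}

#' Write a network edge list as TSV and optional SIF
#' @param edges data.frame from [build_network()]
#' @param path TSV output path
#' @param sif optional SIF output path for graph viewers
#' @export
write_network_tsv <- function(edges, path, sif = NULL) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sif))
    writeLines(sprintf("%s %s %s", edges$otu_a, edges$sign, edges$otu_b),
               sif)
  invisible(path)
}
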