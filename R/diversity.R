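#' Shannon diversity (natural log)
#'
#' H = -sum p_i ln p_i over taxa with nonzero counts. Invariant under
#' scaling of the count vector; zero for a single-taxon sample.
#'
#' @param counts non-negative vector with positive sum
#' @param base logarithm base (default e, the mothur convention)
#' @return Shannon index in nats (or the chosen base)
#' @export
shannon <- function(counts, base = exp(1)) {
  if (sum(counts) <= 0) stop("all-zero count vector")
  unname(vegan::diversity(counts, index = "shannon", base = base))
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator. Taxa with count > `rare_cutoff` are
#' "abundant" (S_abund); the rest are rare with frequency counts F_i,
#' S_rare rare taxa and N_rare rare individuals. With sample coverage
#' C_ace = 1 - F1/N_rare and the rare-taxon coefficient of variation
#' gamma^2 = max(S_rare/C_ace * sum i(i-1)F_i / (N_rare (N_rare - 1)) - 1, 0),
#' ACE = S_abund + S_rare/C_ace + F1/C_ace * gamma^2. When there are no
#' rare taxa the observed richness is returned; when every rare taxon is a
#' singleton (C_ace = 0) the estimator is undefined and Chao1 is returned
#' instead.
#'
#' @param counts non-negative integer vector with positive sum
#' @param rare_cutoff abundance cutoff separating rare taxa (default 10)
#' @return estimated richness
#' @export
ace <- function(counts, rare_cutoff = 10) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("all-zero count vector")
  rare <- counts[counts <= rare_cutoff]
  s_abund <- sum(counts > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    # all rare taxa are singletons: fall back to Chao1
    f2 <- sum(counts == 2)
    return(length(counts) + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
  i <- seq_len(rare_cutoff)
  f_i <- vapply(i, function(k) sum(rare == k), numeric(1))
  gamma2 <- if (n_rare > 1)
    max(s_rare / c_ace * sum(i * (i - 1) * f_i) / (n_rare * (n_rare - 1)) - 1, 0)
  else 0
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Two-sided Welch t-test
#'
#' Wraps [stats::t.test()] with unequal variances. The degenerate case of
#' two zero-variance groups is handled explicitly: identical constants give
#' t = 0, p = 1; shifted constants give an infinite statistic and a p-value
#' reported at the machine floor, with a warning.
#'
#' @param a,b numeric vectors, each of length >= 2
#' @return list(t, df, p)
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    warning("zero within-group variance with unequal means; p at machine floor")
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                p = .Machine$double.xmin))
  }
  fit <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Per-sample alpha-diversity table
#'
#' @param otu an [otu_tab()] (typically rarefied to a common depth first)
#' @param rare_cutoff ACE rare-taxon cutoff (default 10)
#' @return data.frame(sample_id, observed_otus, shannon, ace)
#' @export
alpha_diversity <- function(otu, rare_cutoff = 10) {
  counts <- otu$counts
  data.frame(
    sample_id = rownames(counts),
    observed_otus = as.integer(rowSums(counts > 0)),
    shannon = apply(counts, 1, shannon),
    ace = apply(counts, 1, ace, rare_cutoff = rare_cutoff),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise group comparisons of alpha-diversity indices
#'
#' Welch t-tests for every pair of groups and each index, with
#' Benjamini-Hochberg correction across comparisons within an index.
#'
#' @param alpha data.frame from [alpha_diversity()]
#' @param groups group label per row of `alpha`
#' @param indices which index columns to compare
#' @return data.frame(index, group_a, group_b, t, df, p, p_adj)
#' @export
compare_alpha <- function(alpha, groups,
                          indices = c("shannon", "ace")) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(alpha))
  lev <- unique(groups)
  rows <- list()
  for (idx in indices) {
    pr <- utils::combn(lev, 2, simplify = FALSE)
    res <- lapply(pr, function(gp) {
      wt <- welch_t(alpha[[idx]][groups == gp[1]],
                    alpha[[idx]][groups == gp[2]])
      data.frame(index = idx, group_a = gp[1], group_b = gp[2],
                 t = wt$t, df = wt$df, p = wt$p,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_adj <- stats::p.adjust(res$p, method = "BH")
    rows[[idx]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
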