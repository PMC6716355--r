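#' Kruskal-Wallis rank-sum test
#'
#' Midrank-corrected H statistic with a chi-square reference on
#' (#groups - 1) degrees of freedom, via [stats::kruskal.test()].
#'
#' @param values numeric vector
#' @param groups group label per value; >= 2 non-empty groups, total n >= 3
#' @return list(H, p)
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2)
    stop("need at least two non-empty groups")
  if (length(values) < 3) stop("total n must be at least 3")
  if (length(unique(values)) == 1)  # all tied: no evidence against the null
    return(list(H = 0, p = 1))
  fit <- stats::kruskal.test(values, groups)
  list(H = unname(fit$statistic), p = fit$p.value)
}

# scale a sample x feature matrix to per-million relative abundances
to_per_million <- function(x) {
  s <- rowSums(x)
  if (any(s == 0)) stop("zero-total sample")
  sweep(x, 1, s, "/") * 1e6
}

#' Bootstrapped linear-discriminant effect sizes
#'
#' For each bootstrap round, a fraction of samples is drawn per class and a
#' one-axis linear discriminant is fitted for every class pair: the
#' class-mean difference direction under the pooled within-class covariance,
#' regularized by adding 1e-6 to the diagonal and normalized to unit length.
#' A feature's effect is the average of the absolute projected class-mean
#' difference attributed to it and its absolute raw class-mean difference.
#' The reported score is log10 of the bootstrap-mean effect (floored at 1),
#' maximized over class pairs, so on per-million input it lands on the
#' familiar log10 LDA-score scale where 4.0 is a strong biomarker.
#'
#' @param x sample x feature matrix of per-million relative abundances
#' @param classes class label per sample; every class needs >= 2 samples
#' @param n_boot bootstrap rounds (default 30)
#' @param boot_fraction fraction of samples drawn per class (default 2/3)
#' @param seed integer seed
#' @return named numeric vector of log10 effect sizes per feature
#' @export
lda_effect_size <- function(x, classes, n_boot = 30, boot_fraction = 2 / 3,
                            seed = 1) {
  x <- as.matrix(x)
  classes <- as.factor(classes)
  if (nlevels(classes) < 2) stop("need at least two classes")
  if (any(table(classes) < 2)) stop("every class needs n >= 2 samples")
  pairs <- utils::combn(levels(classes), 2, simplify = FALSE)
  p <- ncol(x)
  eff <- array(0, dim = c(length(pairs), p))
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(levels(classes), function(cl) {
        i <- which(classes == cl)
        take <- max(2L, ceiling(boot_fraction * length(i)))
        sample(i, min(take, length(i)))
      }))
      xb <- x[idx, , drop = FALSE]
      cb <- classes[idx]
      for (k in seq_along(pairs)) {
        ia <- which(cb == pairs[[k]][1])
        ib <- which(cb == pairs[[k]][2])
        xa <- xb[ia, , drop = FALSE]
        xbm <- xb[ib, , drop = FALSE]
        d <- colMeans(xa) - colMeans(xbm)
        if (all(d == 0)) next
        sw <- (stats::cov(xa) * (nrow(xa) - 1) +
               stats::cov(xbm) * (nrow(xbm) - 1)) /
          max(nrow(xa) + nrow(xbm) - 2, 1)
        diag(sw) <- diag(sw) + 1e-6
        w <- tryCatch(solve(sw, d), error = function(e) d)
        w <- w / sqrt(sum(w^2))
        projdiff <- sum(w * d)
        eff[k, ] <- eff[k, ] + (abs(w * projdiff) + abs(d)) / 2
      }
    }
  })
  eff <- eff / n_boot
  scores <- log10(pmax(apply(eff, 2, max), 1))
  stats::setNames(scores, colnames(x))
}

#' LEfSe-style biomarker discovery
#'
#' Features are first screened with a Kruskal-Wallis test at `alpha` on
#' per-million relative abundances; survivors are scored with
#' [lda_effect_size()]. A feature passes when its screen p-value is below
#' `alpha` and its log10 LDA score is at least `lda_threshold` (4.0, the
#' study's cutoff). No subclass stage is applied.
#'
#' @param x an [otu_tab()] or a sample x feature count/abundance matrix
#' @param classes class label per sample (e.g. cultivation stage)
#' @param alpha Kruskal-Wallis screen level (default 0.05)
#' @param lda_threshold log10 LDA score threshold (default 4.0)
#' @param n_boot,boot_fraction,seed passed to [lda_effect_size()]
#' @return data.frame(feature_id, kw_p, lda_score, enriched_class, passes),
#'   sorted by decreasing LDA score; screened-out features carry NA scores
#' @export
run_lefse <- function(x, classes, alpha = 0.05, lda_threshold = 4.0,
                      n_boot = 30, boot_fraction = 2 / 3, seed = 1) {
  counts <- if (inherits(x, "otu_tab")) x$counts else as.matrix(x)
  classes <- as.factor(classes)
  if (nlevels(classes) < 2) stop("need at least two classes")
  stopifnot(length(classes) == nrow(counts))
  ppm <- to_per_million(counts)
  kw_p <- apply(ppm, 2, function(v) kruskal_wallis(v, classes)$p)
  class_means <- vapply(levels(classes), function(cl)
    colMeans(ppm[classes == cl, , drop = FALSE]), numeric(ncol(ppm)))
  if (!is.matrix(class_means))
    class_means <- matrix(class_means, nrow = ncol(ppm))
  enriched <- levels(classes)[max.col(class_means, ties.method = "first")]
  survivors <- names(kw_p)[kw_p < alpha]
  scores <- stats::setNames(rep(NA_real_, ncol(ppm)), colnames(ppm))
  if (length(survivors) > 0)
    scores[survivors] <- lda_effect_size(
      ppm[, survivors, drop = FALSE], classes,
      n_boot = n_boot, boot_fraction = boot_fraction, seed = seed)
  out <- data.frame(feature_id = colnames(ppm),
                    kw_p = unname(kw_p),
                    lda_score = unname(scores),
                    enriched_class = enriched,
                    stringsAsFactors = FALSE)
  out$passes <- !is.na(out$lda_score) & out$kw_p < alpha &
    out$lda_score >= lda_threshold
  out <- out[order(-ifelse(is.na(out$lda_score), -Inf, out$lda_score)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
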