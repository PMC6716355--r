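# Shared fixtures and independent oracles, all built in code.

# build a uniqueseq_table from a plain sample x sequence count matrix,
# inventing distinct sequence strings when none are supplied
make_table <- function(counts, control_ids = character(), sequences = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("u%02d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  if (is.null(sequences)) {
    pool <- withr::with_seed(42, vapply(seq_len(ncol(counts)), function(i)
      paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""),
      character(1)))
    sequences <- stats::setNames(pool, colnames(counts))
  }
  uniqueseq_table(counts, sequences, control_ids)
}

# straight-line reference implementation of the four-step decontamination,
# written with explicit loops, independent of the package's matrix code path
oracle_decontam <- function(counts, control_ids,
                            ratio = 10, minab = 0.001, maxf = 0.75) {
  start <- rowSums(counts)
  repeat {
    n_seq_before <- ncol(counts)
    n_smp_before <- nrow(counts)
    ctl <- intersect(rownames(counts), control_ids)
    expm <- setdiff(rownames(counts), ctl)

    rel <- counts * 0
    for (s in rownames(counts)) {
      tot <- sum(counts[s, ])
      if (tot > 0) rel[s, ] <- counts[s, ] / tot
    }
    # step 1: 10x control rule
    keep1 <- character(0)
    for (u in colnames(counts)) {
      mc <- 0
      for (s in ctl) mc <- max(mc, rel[s, u])
      ok <- FALSE
      for (s in expm) if (rel[s, u] > 0 && rel[s, u] >= ratio * mc) ok <- TRUE
      if (ok) keep1 <- c(keep1, u)
    }
    counts <- counts[, keep1, drop = FALSE]
    # step 2: 0.1% floor on current experimental library sizes
    keep2 <- character(0)
    for (u in colnames(counts)) {
      ok <- FALSE
      for (s in expm) {
        tot <- sum(counts[s, ])
        if (tot > 0 && counts[s, u] / tot >= minab) ok <- TRUE
      }
      if (ok) keep2 <- c(keep2, u)
    }
    counts <- counts[, keep2, drop = FALSE]
    # step 3: over-filtered samples out, against starting sizes
    keep3 <- character(0)
    for (s in rownames(counts))
      if (sum(counts[s, ]) / start[s] >= 1 - maxf) keep3 <- c(keep3, s)
    counts <- counts[keep3, , drop = FALSE]

    no_removal <- ncol(counts) == n_seq_before && nrow(counts) == n_smp_before
    empty <- ncol(counts) == 0 || nrow(counts) == 0
    no_experimental <- length(setdiff(rownames(counts), control_ids)) == 0
    if (no_removal || empty || no_experimental) break
  }
  counts
}

# random small table with at least one control and one experimental sample;
# a mix of control-enriched, genuine-looking and rare sequences
random_small_table <- function(seed, max_dim = 10) {
  withr::with_seed(seed, {
    n_s <- sample(3:max_dim, 1)
    n_u <- sample(3:max_dim, 1)
    n_ctl <- sample(1:(n_s - 1), 1)
    counts <- matrix(stats::rpois(n_s * n_u, lambda = 40), n_s, n_u)
    # sprinkle zeros and rare counts so every rule can fire
    counts[stats::runif(length(counts)) < 0.3] <- 0L
    counts[stats::runif(length(counts)) < 0.2] <- 1L
    counts[rowSums(counts) == 0, 1] <- 5L
    rownames(counts) <- sprintf("s%02d", seq_len(n_s))
    colnames(counts) <- sprintf("u%02d", seq_len(n_u))
    make_table(counts, control_ids = rownames(counts)[seq_len(n_ctl)])
  })
}

# small stage-labelled count matrix with one strongly planted marker per
# stage; non-markers share a common mean across stages
planted_marker_counts <- function(seed, n_per_stage = 6, n_features = 50,
                                  stages = c("I", "V", "VI", "VII"),
                                  marker_share = 0.05, base_depth = 20000) {
  withr::with_seed(seed, {
    groups <- rep(stages, each = n_per_stage)
    markers <- stats::setNames(sprintf("f%02d", seq_along(stages)), stages)
    probs_base <- rep(1, n_features)
    counts <- t(vapply(groups, function(st) {
      p <- probs_base
      p[seq_along(stages)] <- 0.02          # markers scarce by default
      p[match(markers[[st]], sprintf("f%02d", seq_len(n_features)))] <-
        marker_share * sum(p) / (1 - marker_share)
      stats::rmultinom(1, base_depth, p / sum(p))[, 1]
    }, integer(n_features)))
    rownames(counts) <- sprintf("%s_%d", groups, seq_along(groups))
    colnames(counts) <- sprintf("f%02d", seq_len(n_features))
    list(counts = counts, groups = groups, markers = markers)
  })
}

# minimal design + profiles for fast end-to-end runs
small_sim <- function(seed = 7, ...) {
  design <- enumerate_design()
  profiles <- make_stage_profiles(n_taxa = 20, seed = seed)
  simulate_counts(design, profiles, depth_range = c(2000, 3000),
                  n_noise = 10, noise_fraction = 0.002, seed = seed, ...)
}
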