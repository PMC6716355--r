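#' Enumerate the staged cultivation sampling design
#'
#' Builds the full 150-sample design of the casing-soil cultivation study:
#' six replicate culture bottles sampled across stages I-VII (stage IV, the
#' casing step itself, is not sampled). Under the normal-casing treatment,
#' stage I contributes casing soil only; stages II-III contribute upper and
#' lower substrate; stages V-VI add casing soil; stage VII adds fruit
#' bodies. The no-casing and sterilized-casing treatments are sampled at
#' stages V-VI with the same strategy (no casing-soil compartment under
#' no-casing). Stage II libraries of the normal treatment come from
#' substrate sterilized at 121 degrees C and act as negative controls for
#' decontamination.
#'
#' @param n_reps replicate bottles per condition (default 6)
#' @return data.frame with columns `sample_id`, `stage` (I/II/III/V/VI/VII),
#'   `compartment` (casing_soil/upper_substrate/lower_substrate/fruit_body),
#'   `treatment` (normal/no_casing/sterilized), `is_negative_control`.
#' @export
enumerate_design <- function(n_reps = 6) {
  comps <- list(
    normal = list(I = "casing_soil",
                  II = c("upper_substrate", "lower_substrate"),
                  III = c("upper_substrate", "lower_substrate"),
                  V = c("casing_soil", "upper_substrate", "lower_substrate"),
                  VI = c("casing_soil", "upper_substrate", "lower_substrate"),
                  VII = c("casing_soil", "upper_substrate", "lower_substrate",
                          "fruit_body")),
    no_casing = list(V = c("upper_substrate", "lower_substrate"),
                     VI = c("upper_substrate", "lower_substrate")),
    sterilized = list(V = c("casing_soil", "upper_substrate", "lower_substrate"),
                      VI = c("casing_soil", "upper_substrate", "lower_substrate")))
  code <- c(normal = "N", no_casing = "NC", sterilized = "S")
  rows <- list()
  for (tr in names(comps)) {
    for (st in names(comps[[tr]])) {
      for (cp in comps[[tr]][[st]]) {
        cp_code <- c(casing_soil = "CS", upper_substrate = "U",
                     lower_substrate = "L", fruit_body = "FB")[[cp]]
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_%s_r%d", code[[tr]], st, cp_code,
                              seq_len(n_reps)),
          stage = st, compartment = cp, treatment = tr,
          stringsAsFactors = FALSE)
      }
    }
  }
  design <- do.call(rbind, rows)
  design$is_negative_control <- design$stage == "II" &
    design$treatment == "normal"
  rownames(design) <- NULL
  design
}

# seeded Dirichlet draw (gamma normalization)
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Stage- and compartment-structured community profiles
#'
#' Generates one relative-abundance profile per (stage, compartment)
#' combination in the sampling design. Casing-soil profiles embed the
#' dominant-genus trajectory reported for the cultivation stages: a
#' Burkholderia-like taxon at 11.95% in original casing soil (stage I),
#' 55.79% at full hyphal colonization (stage V), 35.14% at the primordial
#' stage (stage VI) and 45.60% at fruiting (stage VII), plus a
#' Thermogemmatispora-like taxon declining from 26.68% to 1.10%. The
#' remaining mass is spread over the other taxa by a seeded Dirichlet draw,
#' independently per profile, so stages genuinely differ and group tests
#' have signal.
#'
#' @param n_taxa number of genuine taxa (>= 10)
#' @param seed integer seed for the Dirichlet draws
#' @param dirichlet_conc total Dirichlet concentration spread over the
#'   non-anchored taxa; larger values give flatter tails (default 200)
#' @return object of class `stage_profiles`: a named list keyed
#'   `"<stage>:<compartment>"` of named abundance vectors, each summing to 1.
#' @export
make_stage_profiles <- function(n_taxa = 50, seed = 1, dirichlet_conc = 200) {
  if (n_taxa < 10) stop("n_taxa must be at least 10 to host the anchored taxa")
  taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  # printed casing-soil trajectories for the two anchored taxa
  dom1 <- c(I = 0.1195, V = 0.5579, VI = 0.3514, VII = 0.4560)
  dom2 <- c(I = 0.2668, V = 0.0570, VI = 0.0300, VII = 0.0110)
  design <- enumerate_design()
  keys <- unique(paste(design$stage, design$compartment, sep = ":"))
  stages <- c("I", "II", "III", "V", "VI", "VII")
  profiles <- withr::with_seed(seed, {
    out <- list()
    for (key in keys) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      st <- parts[1]; cp <- parts[2]
      p <- stats::setNames(numeric(n_taxa), taxa)
      if (cp == "casing_soil" && st %in% names(dom1)) {
        p[1] <- dom1[[st]]
        p[2] <- dom2[[st]]
        rest <- rdirichlet1(rep(dirichlet_conc / (n_taxa - 2), n_taxa - 2))
        p[3:n_taxa] <- rest * (1 - p[1] - p[2])
      } else {
        # substrate / fruit-body profiles: one stage-specific dominant taxon
        alpha <- rep(dirichlet_conc / n_taxa, n_taxa)
        lead <- 3L + (match(st, stages) - 1L) %% (n_taxa - 3L)
        alpha[lead] <- alpha[lead] * 25
        p[] <- rdirichlet1(alpha)
      }
      out[[key]] <- p
    }
    out
  })
  structure(profiles, class = "stage_profiles", taxa = taxa)
}

random_dna <- function(n, len = 250) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate contaminated amplicon count tables with ground truth
#'
#' Draws one library per design sample as a single multinomial of the
#' sample's stage/compartment profile (genuine sequences), a contaminant
#' profile shared across all samples (the reagent-contamination model, with
#' per-sample amplitude scaled by a lognormal factor), and sample-private
#' low-abundance noise sequences each kept below 0.1% expected relative
#' abundance. Negative-control samples draw from the contaminant profile
#' only, emulating sterilized substrate whose free DNA still amplifies.
#'
#' @param design data.frame from [enumerate_design()]
#' @param profiles `stage_profiles` from [make_stage_profiles()]
#' @param n_contaminants number of shared contaminant sequences
#' @param contamination_fraction expected contaminant share of an
#'   experimental library, in \[0, 1)
#' @param noise_fraction total expected noise share per experimental library;
#'   split evenly over `n_noise` private sequences
#' @param n_noise private noise sequences per sample; `noise_fraction /
#'   n_noise` must stay below 0.001
#' @param depth_range integer pair; per-sample depth is uniform on this range
#' @param contam_sd lognormal sigma of the per-sample contamination amplitude
#' @param seed integer seed
#' @return list with `table` (a [uniqueseq_table()]) and `truth` (data.frame
#'   `sequence_id`, `origin` in genuine/contaminant/noise)
#' @export
simulate_counts <- function(design, profiles,
                            n_contaminants = 10,
                            contamination_fraction = 0.02,
                            noise_fraction = 0.002,
                            n_noise = 40,
                            depth_range = c(20000, 40000),
                            contam_sd = 0.3,
                            seed = 1) {
  stopifnot(contamination_fraction >= 0, contamination_fraction < 1,
            noise_fraction >= 0, noise_fraction < 1,
            all(depth_range > 0), length(depth_range) == 2)
  if (n_noise > 0 && noise_fraction / n_noise >= 0.001)
    stop("per-sequence noise share must be below 0.1%")
  taxa <- attr(profiles, "taxa")
  n_samples <- nrow(design)
  contam_ids <- sprintf("contam_%02d", seq_len(n_contaminants))
  noise_ids <- as.vector(outer(seq_len(n_noise), design$sample_id,
                               function(j, s) sprintf("noise_%s_%02d", s, j)))
  seq_ids <- c(taxa, contam_ids, noise_ids)

  withr::with_seed(seed, {
    seq_strings <- stats::setNames(random_dna(length(seq_ids)), seq_ids)
    contam_profile <- rdirichlet1(rep(2, n_contaminants))
    counts <- matrix(0L, n_samples, length(seq_ids),
                     dimnames = list(design$sample_id, seq_ids))
    for (i in seq_len(n_samples)) {
      depth <- sample(depth_range[1]:depth_range[2], 1)
      sid <- design$sample_id[i]
      if (design$is_negative_control[i]) {
        draw <- stats::rmultinom(1, depth, contam_profile)[, 1]
        counts[i, contam_ids] <- draw
      } else {
        key <- paste(design$stage[i], design$compartment[i], sep = ":")
        p_gen <- profiles[[key]]
        cf <- min(contamination_fraction * stats::rlnorm(1, 0, contam_sd), 0.5)
        my_noise <- sprintf("noise_%s_%02d", sid, seq_len(n_noise))
        probs <- c(p_gen * (1 - cf - noise_fraction),
                   contam_profile * cf,
                   rep(noise_fraction / n_noise, n_noise))
        draw <- stats::rmultinom(1, depth, probs)[, 1]
        counts[i, c(taxa, contam_ids, my_noise)] <- draw
      }
    }
    # drop globally absent sequences (e.g. unused noise slots)
    keep <- colSums(counts) > 0
    counts <- counts[, keep, drop = FALSE]
    truth <- data.frame(
      sequence_id = colnames(counts),
      origin = ifelse(colnames(counts) %in% taxa, "genuine",
                      ifelse(colnames(counts) %in% contam_ids,
                             "contaminant", "noise")),
      stringsAsFactors = FALSE)
    list(table = uniqueseq_table(counts, seq_strings[colnames(counts)],
                                 design$sample_id[design$is_negative_control]),
         truth = truth)
  })
}

#' Deterministic 6-bp barcodes for a set of samples
#'
#' @param sample_ids character vector of sample ids
#' @return named character vector of unique 6-bp barcodes
#' @export
default_barcodes <- function(sample_ids) {
  n <- length(sample_ids)
  if (n > 4^6) stop("more samples than 6-bp barcodes")
  bases <- c("A", "C", "G", "T")
  codes <- vapply(seq_len(n) - 1L, function(k) {
    digits <- integer(6)
    for (j in 6:1) { digits[j] <- k %% 4L; k <- k %/% 4L }
    paste(bases[digits + 1L], collapse = "")
  }, character(1))
  stats::setNames(codes, sample_ids)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write a count table out as paired FASTQ with barcodes and primer
#'
#' Emits R1/R2 read pairs for every counted sequence occurrence. R1 carries
#' the sample's 6-bp barcode, then the forward primer, then the leading
#' `read_length` bases of the template; R2 is the reverse complement of the
#' trailing `read_length` bases. Reads therefore overlap by
#' `2 * read_length - template length` bases, which must be at least 10.
#' Qualities are constant phred+33 Q38; with `error_rate = 0` a full
#' merge/filter/demultiplex/dereplicate run reconstructs the input table
#' exactly.
#'
#' @param table a [uniqueseq_table()]
#' @param barcode_map named character vector sample_id -> unique 6-bp barcode
#' @param dir output directory (created if missing)
#' @param fwd_primer forward primer prepended after the barcode (default the
#'   338F 16S primer)
#' @param read_length length of each mate
#' @param error_rate per-base substitution probability
#' @param seed integer seed (errors only)
#' @return character vector of the two FASTQ paths (R1, R2)
#' @export
write_fastq_pairs <- function(table, barcode_map, dir,
                              fwd_primer = "ACTCCTACGGGAGGCAGCAG",
                              read_length = 160, error_rate = 0, seed = 1) {
  samples <- rownames(table$counts)
  if (!all(samples %in% names(barcode_map)))
    stop("barcode_map must cover every sample")
  bc <- barcode_map[samples]
  if (any(nchar(bc) != 6)) stop("barcodes must be exactly 6 bp")
  if (anyDuplicated(bc)) stop("duplicate barcodes")
  lens <- nchar(table$sequences)
  if (any(2 * read_length - lens < 10))
    stop("mates must overlap by at least 10 bp; increase read_length")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  r1 <- character(0); r2 <- character(0); ids <- character(0)
  for (s in samples) {
    cnt <- table$counts[s, ]
    for (u in names(cnt)[cnt > 0]) {
      seq <- table$sequences[[u]]
      n <- cnt[[u]]
      fwd <- paste0(bc[[s]], fwd_primer, substr(seq, 1, read_length))
      rev <- revcomp(substr(seq, nchar(seq) - read_length + 1, nchar(seq)))
      ids <- c(ids, sprintf("%s.%s.%d", s, u, seq_len(n)))
      r1 <- c(r1, rep(fwd, n))
      r2 <- c(r2, rep(rev, n))
    }
  }
  if (error_rate > 0) {
    mutate <- function(reads) vapply(reads, function(x) {
      ch <- strsplit(x, "")[[1]]
      hit <- stats::runif(length(ch)) < error_rate
      ch[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    withr::with_seed(seed, {
      r1 <- mutate(r1)
      r2 <- mutate(r2)
    })
  }
  p1 <- file.path(dir, "reads_R1.fastq")
  p2 <- file.path(dir, "reads_R2.fastq")
  write_fastq <- function(ids, reads, path) {
    qual <- vapply(nchar(reads), function(n)
      strrep(rawToChar(as.raw(38 + 33)), n), character(1))
    writeLines(as.vector(rbind(paste0("@", ids), reads, "+", qual)), path)
  }
  write_fastq(ids, r1, p1)
  write_fastq(ids, r2, p2)
  c(p1, p2)
}
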