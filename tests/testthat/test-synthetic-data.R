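test_that("the enumerated design reproduces the study's sampling layout", {
  d <- enumerate_design()
  expect_equal(nrow(d), 150)
  expect_equal(as.vector(table(d$treatment)[c("normal", "no_casing", "sterilized")]),
               c(90, 24, 36))
  expect_equal(sum(d$is_negative_control), 12)
  # controls are exactly the stage II normal-treatment substrate samples
  ctl <- d[d$is_negative_control, ]
  expect_true(all(ctl$stage == "II" & ctl$treatment == "normal"))
  expect_setequal(unique(ctl$compartment),
                  c("upper_substrate", "lower_substrate"))
  # combination restrictions: casing soil only where a casing layer exists,
  # fruit bodies only at harvest
  expect_false(any(d$treatment == "no_casing" & d$compartment == "casing_soil"))
  expect_true(all(d$stage[d$compartment == "fruit_body"] == "VII"))
  expect_false(any(d$stage %in% c("II", "III") & d$compartment == "casing_soil"))
  expect_false(anyDuplicated(d$sample_id) > 0)
})

test_that("stage profiles anchor the printed casing-soil trajectories", {
  p <- make_stage_profiles(n_taxa = 50, seed = 1)
  expect_equal(unname(p[["V:casing_soil"]][1]), 0.5579)
  expect_equal(unname(p[["VI:casing_soil"]][1]), 0.3514)
  expect_equal(unname(p[["VII:casing_soil"]][1]), 0.4560)
  expect_equal(unname(p[["I:casing_soil"]][1]), 0.1195)
  for (key in names(p)) {
    expect_equal(sum(p[[key]]), 1, tolerance = 1e-9)
    expect_true(all(p[[key]] >= 0))
  }
  # same seed reproduces; different stages differ
  expect_identical(p, make_stage_profiles(n_taxa = 50, seed = 1))
  expect_gt(sum(abs(p[["V:casing_soil"]] - p[["VI:casing_soil"]])), 0.1)
  expect_error(make_stage_profiles(n_taxa = 5), "at least 10")
})

test_that("simulated counts respect the contamination model by construction", {
  d <- enumerate_design()
  p <- make_stage_profiles(n_taxa = 20, seed = 2)
  sim <- simulate_counts(d, p, depth_range = c(2000, 3000), seed = 7)
  tab <- sim$table
  genuine <- sim$truth$sequence_id[sim$truth$origin == "genuine"]
  contam <- sim$truth$sequence_id[sim$truth$origin == "contaminant"]
  noise <- sim$truth$sequence_id[sim$truth$origin == "noise"]
  is_ctl <- rownames(tab$counts) %in% tab$control_ids
  # negative controls carry contaminant-origin reads only
  expect_true(all(tab$counts[is_ctl, c(genuine, noise)] == 0))
  expect_true(all(rowSums(tab$counts[is_ctl, contam, drop = FALSE]) > 0))
  # library sizes within the requested depth range
  expect_true(all(library_sizes(tab) >= 2000 & library_sizes(tab) <= 3000))
  # deterministic under the seed
  sim2 <- simulate_counts(d, p, depth_range = c(2000, 3000), seed = 7)
  expect_identical(sim$table$counts, sim2$table$counts)
  # no contamination means no contaminant-origin reads outside controls
  clean <- simulate_counts(d, p, contamination_fraction = 0,
                           depth_range = c(2000, 3000), seed = 3)
  cont2 <- clean$truth$sequence_id[clean$truth$origin == "contaminant"]
  exp_rows <- !(rownames(clean$table$counts) %in% clean$table$control_ids)
  if (length(cont2) > 0)
    expect_true(all(clean$table$counts[exp_rows, cont2] == 0))
  expect_error(simulate_counts(d, p, contamination_fraction = 1.2),
               "contamination_fraction")
})

test_that("contaminants are recoverable by design under default settings", {
  # every contaminant's relative abundance in any experimental library stays
  # below a tenth of its best control relative abundance
  sim <- small_sim(seed = 5)
  tab <- sim$table
  rel <- relative_abundance(tab)
  contam <- sim$truth$sequence_id[sim$truth$origin == "contaminant"]
  is_ctl <- rownames(tab$counts) %in% tab$control_ids
  max_ctl <- apply(rel[is_ctl, contam, drop = FALSE], 2, max)
  max_exp <- apply(rel[!is_ctl, contam, drop = FALSE], 2, max)
  expect_true(all(max_exp < max_ctl / 10))
})

test_that("genuine relative abundances are multinomially consistent", {
  d <- enumerate_design()
  d <- d[d$stage == "V" & d$compartment == "casing_soil" &
           d$treatment == "normal", ][1:3, ]
  p <- make_stage_profiles(n_taxa = 20, seed = 4)
  sim <- simulate_counts(d, p, contamination_fraction = 0, noise_fraction = 0,
                         n_noise = 0, depth_range = c(100000, 100000),
                         seed = 11)
  prof <- p[["V:casing_soil"]]
  for (s in rownames(sim$table$counts)) {
    counts <- sim$table$counts[s, names(prof)]
    n <- sum(counts)
    se <- sqrt(prof * (1 - prof) / n)
    expect_true(all(abs(counts / n - prof) <= 3 * se + 1e-12))
  }
})

test_that("FASTQ output is validated, deterministic and lossless", {
  counts <- matrix(c(3, 2, 0, 1, 0, 4), nrow = 2, byrow = TRUE)
  tab <- make_table(counts, sequences = stats::setNames(
    withr::with_seed(9, random_dna <- vapply(1:3, function(i)
      paste(sample(c("A", "C", "G", "T"), 250, replace = TRUE), collapse = ""),
      character(1))), c("u01", "u02", "u03")))
  bc <- default_barcodes(rownames(tab$counts))
  expect_error(write_fastq_pairs(tab, stats::setNames(c("ACGT", "ACGTAA"),
                                                      rownames(tab$counts)),
                                 tempfile()), "6 bp")
  expect_error(write_fastq_pairs(tab, stats::setNames(rep("AAAAAA", 2),
                                                      rownames(tab$counts)),
                                 tempfile()), "duplicate")
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- write_fastq_pairs(tab, bc, d1, seed = 1)
  f2 <- write_fastq_pairs(tab, bc, d2, seed = 1)
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  expect_identical(readLines(f1[2]), readLines(f2[2]))
  # error-free reads round-trip through the full read pipeline
  res <- process_fastq_pairs(f1[1], f1[2], bc)
  reord <- match(tab$sequences, res$table$sequences)
  expect_true(all(!is.na(reord)))
  expect_equal(unname(res$table$counts[rownames(tab$counts), reord]),
               unname(tab$counts))
  expect_equal(res$accounting[["assigned"]], sum(tab$counts))
})
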