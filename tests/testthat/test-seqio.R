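rand_seq <- function(n, seed) withr::with_seed(seed,
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))

test_that("merge_pair finds the best overlap and applies the quality rule", {
  core <- rand_seq(120, 1)
  # mates with an exact 20-bp overlap: seq1 = first 70, seq2 covers last 70
  seq1 <- substr(core, 1, 70)
  seq2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(core, 51, 120))))
  m <- merge_pair(seq1, rep(35L, 70), seq2, rep(35L, 70))
  expect_equal(nchar(m$seq), 70 + 70 - 20)
  expect_equal(m$seq, core)

  # a true 9-bp overlap cannot satisfy the 10-bp minimum: rejection
  s1 <- rand_seq(40, 2)
  tail9 <- substr(s1, 32, 40)
  s2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(tail9, rand_seq(30, 3)))))
  expect_null(merge_pair(s1, rep(35L, 40), s2, rep(35L, 39)))

  # at a mismatching overlap column the higher-quality base wins
  a <- "ACGTACGTACGT"
  b_template <- substr(a, 3, 12)                   # 10-bp overlap
  b_mut <- paste0("T", substr(b_template, 2, 10))  # first overlap base flipped
  b <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b_mut)))
  hi2 <- merge_pair(a, rep(20L, 12), b, rep(39L, 10))
  expect_equal(substr(hi2$seq, 3, 3), "T")   # mate-2 base, higher quality
  hi1 <- merge_pair(a, rep(39L, 12), b, rep(20L, 10))
  expect_equal(substr(hi1$seq, 3, 3), "G")   # mate-1 base kept
})

test_that("qc_filter applies the verbatim length/quality/ambiguity rules", {
  expect_false(qc_filter(rand_seq(199, 4), rep(38L, 199))$pass)
  expect_equal(qc_filter(rand_seq(199, 4), rep(38L, 199))$reason, "length")
  expect_equal(qc_filter(rand_seq(250, 5), rep(30L, 250))$reason, "quality")
  withN <- paste0(substr(rand_seq(250, 6), 1, 249), "N")
  expect_equal(qc_filter(withN, rep(38L, 250))$reason, "ambiguous")
  expect_true(qc_filter(rand_seq(250, 6), rep(38L, 250))$pass)
})

test_that("demultiplexing requires exact barcode and primer matches", {
  primer <- "ACTCCTACGGGAGGCAGCAG"
  bc <- c(sampleA = "AAAAAA", sampleB = "CCCCCC")
  good <- paste0("AAAAAA", primer, "GGGTTT")
  bad_bc <- paste0("AAAAAT", primer, "GGGTTT")
  bad_primer <- paste0("CCCCCC", substr(primer, 1, 19), "T", "GGGTTT")
  res <- demultiplex(c(good, bad_bc, bad_primer), bc, primer)
  expect_equal(res$assigned$sampleA, "GGGTTT")
  expect_equal(length(res$assigned$sampleB), 0)
  expect_equal(res$n_discarded, 2)
  empty <- demultiplex(character(0), bc, primer)
  expect_equal(empty$n_discarded, 0)
  expect_equal(lengths(empty$assigned), c(sampleA = 0L, sampleB = 0L))
  expect_error(demultiplex(good, c(a = "AAAAAA", b = "AAAAAA"), primer),
               "duplicate")
})

test_that("dereplication collapses identical strings deterministically", {
  S <- rand_seq(60, 7); U <- rand_seq(60, 8)
  tab <- dereplicate(list(A = c(S, S, S, U), B = c(S, S)))
  expect_equal(ncol(tab$counts), 2)
  s_col <- which(tab$sequences == S)
  expect_equal(unname(tab$counts[c("A", "B"), s_col]), c(3, 2))
  # totals preserved
  expect_equal(unname(library_sizes(tab)), c(4, 2))
  # all-distinct input gives one column per read
  distinct <- vapply(1:5, function(i) rand_seq(60, 100 + i), character(1))
  expect_equal(ncol(dereplicate(list(A = distinct))$counts), 5)
  # column order is by decreasing total then string, not input order
  tab2 <- dereplicate(list(B = c(S, S), A = c(U, S, S, S)))
  expect_identical(unname(tab2$sequences), unname(tab$sequences))
})

test_that("read accounting is conserved through the pipeline", {
  sim <- small_sim(seed = 2)
  # take a small slice of the simulated table to keep the FASTQ tiny
  keep <- rownames(sim$table$counts)[1:4]
  cols <- colSums(sim$table$counts[keep, , drop = FALSE]) > 0
  tab <- uniqueseq_table(sim$table$counts[keep, cols, drop = FALSE] %/% 50 + 1,
                         sim$table$sequences[cols], character(0))
  bc <- default_barcodes(keep)
  fq <- write_fastq_pairs(tab, bc, tempfile())
  res <- process_fastq_pairs(fq[1], fq[2], bc)
  acct <- res$accounting
  expect_equal(acct[["input"]],
               acct[["assigned"]] + acct[["unassigned"]] +
                 acct[["merge_failed"]] + acct[["qc_failed"]])
  expect_equal(sum(res$table$counts), acct[["assigned"]])
})
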