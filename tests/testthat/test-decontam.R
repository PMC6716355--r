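test_that("relative abundances are computed against current library sizes", {
  tab <- make_table(matrix(c(5, 5, 0, 10), 2, byrow = TRUE))
  rel <- relative_abundance(tab)
  expect_equal(unname(rel[1, ]), c(0.5, 0.5))
  expect_equal(unname(rel[2, ]), c(0, 1))
  expect_true(all(abs(rowSums(rel) - 1) < 1e-12))
  empty <- make_table(matrix(c(5, 5, 0, 0), 2, byrow = TRUE))
  expect_error(relative_abundance(empty), "zero-size")
})

test_that("step 1 keeps sequences 10x above their best control abundance", {
  # control c1 carries u1 at 5%; u1 reaches 60% in e1 (kept) while u2 at 40%
  # of its 5% control level is removed; u3 absent from controls is kept
  counts <- rbind(c1 = c(u1 = 5, u2 = 5, u3 = 0, u4 = 90),
                  e1 = c(u1 = 60, u2 = 0, u3 = 1, u4 = 39),
                  e2 = c(u1 = 0, u2 = 40, u3 = 0, u4 = 60))
  tab <- make_table(counts, control_ids = "c1")
  kept <- step1_control_ratio(tab)
  expect_true("u1" %in% kept)    # 0.60 >= 10 * 0.05 boundary met
  expect_false("u2" %in% kept)   # 0.40 < 0.50
  expect_true("u3" %in% kept)    # absent from controls, present in e1
  expect_error(step1_control_ratio(make_table(counts)), "no negative-control")
})

test_that("step 2 enforces the 0.1% floor over experimental libraries", {
  counts <- rbind(e1 = c(u1 = 2, u2 = 0, u3 = 998),
                  e2 = c(u1 = 1, u2 = 5, u3 = 9994))
  tab <- make_table(counts, control_ids = character())
  kept <- step2_min_abundance(tab)
  expect_true("u1" %in% kept)    # 0.2% of e1 clears the floor
  expect_false("u2" %in% kept)   # at most 0.05% anywhere: removed
  expect_equal(sort(kept), c("u1", "u3"))
})

test_that("step 3 keeps samples retaining at least a quarter of their reads", {
  counts <- rbind(a = c(251, 0), b = c(249, 0), c = c(250, 0))
  tab <- make_table(counts)
  start <- c(a = 1000, b = 1000, c = 1000)
  kept <- step3_sample_retention(tab, start)
  expect_setequal(kept, c("a", "c"))   # exactly 25% retained is kept
  expect_error(step3_sample_retention(tab, start[1:2]), "missing")
})

test_that("a hand-built table loses one sequence or sample per step", {
  # u_cont dominates the control and stays low in experiments (step 1);
  # u_rare never reaches 0.1% of an experimental library (step 2);
  # sample e_bad is mostly contaminant so it drops below 25% (step 3)
  counts <- rbind(
    ctl   = c(u_cont = 995, u_good = 0,    u_ok = 5,    u_rare = 0),
    e_ok  = c(u_cont = 10,  u_good = 5000, u_ok = 4989, u_rare = 1),
    e_bad = c(u_cont = 950, u_good = 30,   u_ok = 20,   u_rare = 0))
  tab <- make_table(counts, control_ids = "ctl")
  res <- run_decontam(tab)
  it1 <- res$report$iterations[[1]]
  expect_equal(it1$removed_sequences_step1, "u_cont")
  expect_equal(it1$removed_sequences_step2, "u_rare")
  expect_equal(it1$removed_samples, c("ctl", "e_bad"))
  expect_equal(res$report$final_retained_samples, "e_ok")
  expect_equal(sort(colnames(res$table$counts)), c("u_good", "u_ok"))
})

test_that("a clean table is already a fixed point and the run is idempotent", {
  # control spreads evenly over 10 sequences (10% each); each sequence is
  # pure in one experimental library, so every keep rule is satisfied with
  # nothing to remove
  counts <- rbind(ctl = rep(10, 10),
                  diag(1000, 10))
  rownames(counts) <- c("ctl", sprintf("e%02d", 1:10))
  colnames(counts) <- sprintf("u%02d", 1:10)
  tab <- make_table(counts, control_ids = "ctl")
  res <- run_decontam(tab)
  expect_equal(res$report$n_iterations, 1)
  expect_identical(res$table$counts, tab$counts)
  # idempotence on an arbitrary table's output
  sim <- small_sim(seed = 3)
  once <- run_decontam(sim$table)
  twice <- run_decontam(once$table)
  expect_identical(twice$table$counts, once$table$counts)
  expect_equal(twice$report$n_iterations, 1)
})

test_that("kept sequences and samples only shrink across iterations", {
  for (seed in 1:5) {
    tab <- random_small_table(seed)
    # random tables may legitimately lose every experimental sample
    res <- suppressWarnings(run_decontam(tab))
    expect_lte(res$report$n_iterations,
               ncol(tab$counts) + nrow(tab$counts))
    prev_after <- Inf
    for (it in res$report$iterations) {
      expect_lte(it$reads_after, it$reads_before)
      expect_lte(it$reads_before, prev_after)
      prev_after <- it$reads_after
      # removal sets within an iteration are disjoint
      expect_length(intersect(it$removed_sequences_step1,
                              it$removed_sequences_step2), 0)
    }
    expect_true(all(res$table$counts >= 0))
    expect_true(all(colnames(res$table$counts) %in% colnames(tab$counts)))
    expect_true(all(rownames(res$table$counts) %in% rownames(tab$counts)))
  }
})

test_that("the matrix implementation matches the straight-line oracle", {
  for (seed in 1:10) {
    tab <- random_small_table(seed)
    got <- suppressWarnings(run_decontam(tab))$table$counts
    want <- oracle_decontam(tab$counts, tab$control_ids)
    expect_identical(got[rownames(want), colnames(want), drop = FALSE] * 1,
                     want * 1, label = paste("seed", seed))
    expect_identical(dim(got), dim(want))
  }
})

test_that("decontamination separates contaminants from genuine sequences", {
  sim <- small_sim(seed = 1)
  res <- run_decontam(sim$table)
  truth <- sim$truth
  contam_reads_before <- sum(sim$table$counts[
    , truth$sequence_id[truth$origin == "contaminant"], drop = FALSE])
  kept_ids <- colnames(res$table$counts)
  contam_kept <- sum(res$table$counts[
    , intersect(kept_ids, truth$sequence_id[truth$origin == "contaminant"]),
    drop = FALSE])
  expect_lt(contam_kept / contam_reads_before, 0.05)
  # every negative control is discarded by step 3, as in the study
  expect_length(intersect(res$report$final_retained_samples,
                          sim$table$control_ids), 0)
})

test_that("report JSON round-trips the accounting", {
  sim <- small_sim(seed = 4)
  res <- run_decontam(sim$table)
  path <- tempfile(fileext = ".json")
  write_decontam_report(res$report, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$retained_read_pct, res$report$retained_read_pct)
  expect_equal(back$total_reads_final, sum(res$table$counts))
})
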