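#' Default pipeline configuration
#'
#' All tunables of the end-to-end run in one list. Every random stage draws
#' its own seed deterministically from `master_seed`.
#'
#' @param master_seed single integer seed for the whole run
#' @param outdir output directory
#' @param table_tsv,meta_tsv optional paths to a pre-dereplicated
#'   unique-sequence table and its sample metadata; when NULL a synthetic
#'   dataset is generated
#' @param n_taxa,contamination_fraction,depth_range synthetic-generator
#'   parameters (see [simulate_counts()])
#' @param control_ratio,min_relabund,max_filtered_fraction decontamination
#'   parameters (see [decontam_params()])
#' @param identity OTU clustering identity threshold
#' @param rarefaction_depth reads per sample after rarefaction
#' @param n_perm ANOSIM permutations
#' @param n_boot LEfSe bootstrap rounds
#' @param lda_threshold LEfSe log10 score threshold
#' @param network_k,rho_threshold,network_alpha co-occurrence network
#'   parameters
#' @param group_column metadata column defining the compared groups
#' @param group_compartment compartment the group tests are restricted to
#' @param group_treatment treatment the group tests are restricted to
#' @return named list of class `pipeline_config`
#' @export
pipeline_config <- function(master_seed = 1,
                            outdir = tempfile("casecomm_run_"),
                            table_tsv = NULL, meta_tsv = NULL,
                            n_taxa = 50,
                            contamination_fraction = 0.02,
                            depth_range = c(20000, 40000),
                            control_ratio = 10,
                            min_relabund = 0.001,
                            max_filtered_fraction = 0.75,
                            identity = 0.97,
                            rarefaction_depth = 7096,
                            n_perm = 999,
                            n_boot = 30,
                            lda_threshold = 4.0,
                            network_k = 20,
                            rho_threshold = 0.75,
                            network_alpha = 0.05,
                            group_column = "stage",
                            group_compartment = "casing_soil",
                            group_treatment = "normal") {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

stage_seed <- function(master, offset) (master * 97L + offset) %% 2147483647L

#' Run the full casing-soil community pipeline
#'
#' simulate (or ingest) -> decontaminate -> cluster -> rarefy ->
#' alpha diversity -> ordination + ANOSIM -> LEfSe -> network.
#' Every stage writes its main artifact under `config$outdir` and the run
#' closes with a machine-readable JSON manifest carrying seeds, parameters
#' and per-stage read accounting. Any stage failure halts with the stage
#' name and cause.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with the in-memory results of every stage plus
#'   the manifest
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = unclass(config), stages = list())
  results <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # 1) input: synthetic simulation or user tables
  if (is.null(config$table_tsv)) {
    sim <- run_stage("simulate", {
      design <- enumerate_design()
      profiles <- make_stage_profiles(
        n_taxa = config$n_taxa,
        seed = stage_seed(config$master_seed, 1L))
      c(simulate_counts(design, profiles,
                        contamination_fraction = config$contamination_fraction,
                        depth_range = config$depth_range,
                        seed = stage_seed(config$master_seed, 2L)),
        list(design = design))
    })
    design <- sim$design
    table <- sim$table
    results$truth <- sim$truth
    write_metadata_tsv(design, file.path(config$outdir, "metadata.tsv"))
  } else {
    design <- run_stage("ingest", read_metadata_tsv(config$meta_tsv))
    table <- run_stage("ingest", read_seqtab_tsv(
      config$table_tsv,
      control_ids = design$sample_id[design$is_negative_control]))
  }
  results$design <- design
  results$table <- table
  manifest$stages$input <- list(
    n_samples = nrow(table$counts),
    n_sequences = ncol(table$counts),
    n_controls = length(table$control_ids),
    total_reads = sum(table$counts))

  # 2) decontamination
  dec <- run_stage("decontam", run_decontam(
    table, decontam_params(config$control_ratio, config$min_relabund,
                           config$max_filtered_fraction)))
  results$decontam <- dec
  write_decontam_report(dec$report,
                        file.path(config$outdir, "decontam_report.json"))
  manifest$stages$decontam <- list(
    n_iterations = dec$report$n_iterations,
    samples_retained = length(dec$report$final_retained_samples),
    retained_read_pct = dec$report$retained_read_pct)

  # 3) clustering
  otu <- run_stage("cluster", greedy_cluster(dec$table, config$identity))
  results$otu <- otu
  write_otutab_tsv(otu, file.path(config$outdir, "otu_table.tsv"),
                   fasta = file.path(config$outdir, "otu_reps.fasta"))
  manifest$stages$cluster <- list(n_otus = ncol(otu$counts))

  # 4) rarefaction
  rare <- run_stage("rarefy", rarefy_table(
    otu, config$rarefaction_depth,
    seed = stage_seed(config$master_seed, 3L)))
  results$rarefied <- rare
  manifest$stages$rarefy <- list(depth = config$rarefaction_depth,
                                 samples_retained = nrow(rare$counts))

  # 5) alpha diversity
  alpha <- run_stage("diversity", alpha_diversity(rare))
  results$alpha <- alpha
  utils::write.table(alpha, file.path(config$outdir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$diversity <- list(n_samples = nrow(alpha))

  # group subset used by all comparative stages
  meta <- design[match(rownames(rare$counts), design$sample_id), ]
  in_grp <- meta$compartment == config$group_compartment &
    meta$treatment == config$group_treatment
  grp <- meta[[config$group_column]][in_grp]
  grp_counts <- rare$counts[in_grp, , drop = FALSE]
  grp_otu <- otu_tab(grp_counts, rare$representatives, rare$members)

  # 6) ordination + ANOSIM
  ord <- run_stage("ordination", {
    d <- bray_curtis(hellinger(grp_counts))
    emb <- nmds(d, seed = stage_seed(config$master_seed, 4L))
    an <- anosim_test(d, grp, n_perm = config$n_perm,
                      seed = stage_seed(config$master_seed, 5L))
    list(dissimilarity = d, nmds = emb, anosim = an)
  })
  results$ordination <- ord
  write_dissimilarity_tsv(ord$dissimilarity,
                          file.path(config$outdir, "bray_curtis.tsv"))
  manifest$stages$ordination <- list(stress = ord$nmds$stress,
                                     converged = ord$nmds$converged)
  manifest$stages$anosim <- list(R = ord$anosim$R, p = ord$anosim$p,
                                 n_permutations = ord$anosim$n_permutations)

  # 7) biomarkers
  lefse <- run_stage("lefse", run_lefse(
    grp_otu, grp, lda_threshold = config$lda_threshold,
    n_boot = config$n_boot,
    seed = stage_seed(config$master_seed, 6L)))
  results$lefse <- lefse
  utils::write.table(lefse, file.path(config$outdir, "lefse.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$lefse <- list(n_passing = sum(lefse$passes))

  # 8) network
  edges <- run_stage("network", build_network(
    rare, k = config$network_k, rho_threshold = config$rho_threshold,
    alpha = config$network_alpha))
  results$network <- edges
  write_network_tsv(edges, file.path(config$outdir, "network_edges.tsv"),
                    sif = file.path(config$outdir, "network.sif"))
  manifest$stages$network <- list(
    n_edges = nrow(edges),
    n_positive = sum(edges$sign == "positive"),
    n_negative = sum(edges$sign == "negative"))

  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}
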