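#' Derive a per-stage seed from the master seed
#'
#' Stable arithmetic hash of `(master_seed, stage name)` so stage-level
#' reruns reproduce pipeline-level results regardless of execution order.
#' The result always fits a 32-bit integer.
#'
#' @param master_seed integer master seed.
#' @param stage stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(master_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(master_seed)) %% 1000003 * 1000003 + h) %%
               2147483647)
}

#' Default pipeline configuration
#'
#' Thresholds follow the screening procedure's defaults (`mind`, `geno`,
#' `maf` 0.05; presence in at least 12 genotyped animals; consensus
#' `h2 > 0.7`, `p < 0.05`; 100 permutations for the heritability null,
#' 1000 for the correlation null, 100 random subsets for the similarity
#' null). The simulate block, when present, drives the synthetic-data
#' module; otherwise the four input paths must point at existing files.
#'
#' @param ... overrides for any top-level entry.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    mind = 0.05, geno = 0.05, maf = 0.05,
    min_present = 12L, h2_min = 0.7, alpha = 0.05,
    n_perm_fdr = 100L, n_perm_corr = 1000L, n_draws_phylo = 100L,
    diagonal_mode = "uniform",
    scoring = list(match = 2, mismatch = -1, gap_open = -5,
                   gap_extend = -2),
    simulate = list(n_animals = 78L, n_genotyped = 47L,
                    families = c(4L, 3L, rep(2L, 9L)), n_snps = 5000L,
                    missing_rate = 0.01, n_otus = 500L, n_heritable = 10L,
                    true_h2 = 0.85, n_days = 3L, clade_identity = 0.90,
                    background_identity = 0.75, n_indices = 8L, snr = 2),
    ped = NULL, map = NULL, otu_table = NULL, fasta = NULL, traits = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

.outputs_exist <- function(paths) length(paths) > 0 &&
  all(file.exists(unlist(paths)))

#' Run the full screening pipeline
#'
#' Orchestrates simulate (optional) -> genotype QC -> GRM -> presence
#' filter and three-day consensus screen (with the permutation FDR null)
#' -> 16S similarity null and taxon enrichment -> trait association and
#' odds-ratio enrichment -> trait heritability, writing every result as
#' TSV under `out_dir` and recording inputs, seeds, config and file digests
#' in `manifest.json`. Stages whose outputs already exist are skipped
#' unless `force = TRUE`; all randomness derives from the master seed via
#' [stage_seed()], so two runs with the same seed produce byte-identical
#' outputs.
#'
#' @param config list from [default_config()] or a path to a YAML file with
#'   the same structure.
#' @param out_dir output directory (created if needed).
#' @param force rerun stages whose outputs already exist.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config(), out_dir, force = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- utils::modifyList(default_config(),
                                yaml::read_yaml(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, paste0(...))
  manifest <- list(config = config, seeds = list(), stages = list(),
                   files = list())
  seeds <- list()
  for (st in c("simulate", "screen", "phylo", "associate"))
    seeds[[st]] <- stage_seed(config$seed, st)
  manifest$seeds <- seeds

  # ---- stage: simulate (optional) ----------------------------------------
  sim_files <- list(ped = pth("synthetic.ped"), map = pth("synthetic.map"),
                    otu = pth("otu_table.tsv"), fasta = pth("otus.fasta"),
                    traits = pth("traits.tsv"), truth = pth("truth.tsv"))
  spec <- NULL
  if (!is.null(config$simulate)) {
    sb <- config$simulate
    if (force || !.outputs_exist(sim_files)) {
      design <- herd_design(
        n_animals = sb$n_animals, n_genotyped = sb$n_genotyped,
        families = sb$families, n_snps = sb$n_snps,
        missing_rate = sb$missing_rate, seed = seeds$simulate)
      sim <- simulate_genotypes(design)
      write_plink(sim$genotypes, sim_files$ped, sim_files$map)
      spec <- planted_microbiome(
        n_otus = sb$n_otus, n_days = sb$n_days,
        n_heritable = sb$n_heritable, true_h2 = sb$true_h2,
        clade_identity = sb$clade_identity,
        background_identity = sb$background_identity,
        seed = seeds$simulate + 1L)
      # plant the signal through the realized GRM the screen will use,
      # embedded so non-genotyped cohort animals get unrelated latents
      qc_sim <- apply_qc(sim$genotypes, mind = config$mind,
                         geno = config$geno, maf = config$maf)
      a_real <- compute_grm(qc_sim$genotypes,
                            diagonal_mode = config$diagonal_mode)
      cohort <- embed_relatedness(a_real, sim$pedigree$ids$iid)
      abund <- simulate_abundances(cohort, spec)
      write_otu_table(abund, sim_files$otu)
      write_fasta(simulate_sequences(spec), sim_files$fasta)
      linkage <- example_trait_linkage(abund, spec$heritable_ids,
                                       n_indices = sb$n_indices,
                                       snr = sb$snr,
                                       seed = seeds$simulate + 2L)
      write_trait_table(simulate_traits(abund, linkage), sim_files$traits)
      write_ground_truth(spec, sim_files$truth)
      .log_stage("simulate", "wrote synthetic cohort: ",
                 sb$n_animals, " animals, ", sb$n_otus, " OTUs")
    } else .log_stage("simulate", "outputs exist, skipped")
    config$ped <- sim_files$ped; config$map <- sim_files$map
    config$otu_table <- sim_files$otu; config$fasta <- sim_files$fasta
    config$traits <- sim_files$traits
    manifest$stages$simulate <- sim_files
  }
  for (f in c("ped", "map", "otu_table", "fasta", "traits"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("pipeline input '", f, "' missing", call. = FALSE)

  # ---- stage: qc ----------------------------------------------------------
  qc_files <- list(ped = pth("qc.ped"), map = pth("qc.map"),
                   report = pth("qc_report.tsv"))
  if (force || !.outputs_exist(qc_files)) {
    g <- read_plink(config$ped, config$map)
    qc <- apply_qc(g, mind = config$mind, geno = config$geno,
                   maf = config$maf)
    write_plink(qc$genotypes, qc_files$ped, qc_files$map)
    write_qc_report(qc$report, qc_files$report)
    .log_stage("qc", "SNPs passing: ", qc$report$snps_pass, " of ",
               qc$report$n_input_snps)
  } else .log_stage("qc", "outputs exist, skipped")
  manifest$stages$qc <- qc_files

  # ---- stage: grm ---------------------------------------------------------
  grm_prefix <- pth("cohort")
  grm_files <- list(id = paste0(grm_prefix, ".grm.id"),
                    gz = paste0(grm_prefix, ".grm.gz"))
  if (force || !.outputs_exist(grm_files)) {
    g <- read_plink(qc_files$ped, qc_files$map)
    a <- compute_grm(g, diagonal_mode = config$diagonal_mode)
    write_grm(a, grm_prefix)
    .log_stage("grm", nrow(a$A), " animals, mean diagonal ",
               signif(mean(diag(a$A)), 4))
  } else .log_stage("grm", "outputs exist, skipped")
  manifest$stages$grm <- grm_files

  # ---- stage: screen (+ permutation FDR) ----------------------------------
  screen_files <- list(results = pth("screen_results.tsv"),
                       consensus = pth("consensus_otus.tsv"),
                       fdr = pth("permutation_fdr.tsv"))
  if (force || !.outputs_exist(screen_files)) {
    a <- read_grm(grm_prefix)
    tab <- read_otu_table(config$otu_table)
    filtered <- presence_filter(tab, a$ids$iid,
                                min_present = config$min_present)
    .log_stage("screen", "OTUs surviving presence filter: ",
               nrow(filtered$values), " of ", nrow(tab$values))
    scr <- screen_heritable(filtered, a, h2_min = config$h2_min,
                            alpha = config$alpha)
    write.table(scr$results, screen_files$results, sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(c("otu_id", scr$consensus), screen_files$consensus)
    fdr <- permutation_fdr(filtered, a, n_perm = config$n_perm_fdr,
                           seed = seeds$screen, h2_min = config$h2_min,
                           alpha = config$alpha)
    write.table(
      data.frame(iteration = c(0L, seq_len(fdr$n_perm)),
                 heritable_count = c(fdr$observed, fdr$perm_counts),
                 type = c("observed", rep("permuted", fdr$n_perm))),
      screen_files$fdr, sep = "\t", quote = FALSE, row.names = FALSE)
    .log_stage("screen", "consensus heritable OTUs: ",
               length(scr$consensus), "; permutations below observed: ",
               round(100 * fdr$fraction_below), "%")
  } else .log_stage("screen", "outputs exist, skipped")
  manifest$stages$screen <- screen_files

  # ---- stage: phylo -------------------------------------------------------
  phylo_files <- list(similarity = pth("similarity_null.tsv"),
                      enrichment = pth("taxon_enrichment.tsv"))
  if (force || !.outputs_exist(phylo_files)) {
    a <- read_grm(grm_prefix)
    tab <- read_otu_table(config$otu_table)
    filtered <- presence_filter(tab, a$ids$iid,
                                min_present = config$min_present)
    consensus <- readLines(screen_files$consensus)[-1L]
    scoring <- do.call(alignment_scoring, config$scoring)
    taxo <- setNames(filtered$otus$taxonomy, filtered$otus$otu_id)
    seqs <- read_fasta(config$fasta, taxonomy = taxo)
    if (length(consensus) >= 2L &&
        length(filtered$otus$otu_id) > length(consensus)) {
      nul <- similarity_null_test(seqs, consensus, filtered$otus$otu_id,
                                  n_draws = config$n_draws_phylo,
                                  seed = seeds$phylo, scoring = scoring)
      write.table(
        data.frame(draw = c(0L, seq_len(nul$n_draws)),
                   mean_similarity = c(nul$observed, nul$null_means),
                   type = c("observed", rep("null", nul$n_draws)),
                   p_value = nul$p_value),
        phylo_files$similarity, sep = "\t", quote = FALSE,
        row.names = FALSE)
      .log_stage("phylo", "observed mean similarity ",
                 round(nul$observed, 1), "%, empirical p ",
                 signif(nul$p_value, 3))
      enr <- taxon_enrichment(taxo, consensus, rank = "order")
      write.table(enr, phylo_files$enrichment, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    } else {
      writeLines("draw\tmean_similarity\ttype\tp_value",
                 phylo_files$similarity)
      writeLines(paste("taxon", "heritable_in", "heritable_out", "other_in",
                       "other_out", "odds_ratio", "p_value", sep = "\t"),
                 phylo_files$enrichment)
      .log_stage("phylo", "fewer than 2 consensus OTUs; wrote empty tables")
    }
  } else .log_stage("phylo", "outputs exist, skipped")
  manifest$stages$phylo <- phylo_files

  # ---- stage: associate ---------------------------------------------------
  assoc_files <- list(correlations = pth("correlations.tsv"),
                      summary = pth("index_summary.tsv"),
                      traits_h2 = pth("trait_heritability.tsv"))
  if (force || !.outputs_exist(assoc_files)) {
    a <- read_grm(grm_prefix)
    tab <- read_otu_table(config$otu_table)
    filtered <- presence_filter(tab, a$ids$iid,
                                min_present = config$min_present)
    consensus <- readLines(screen_files$consensus)[-1L]
    traits <- read_trait_table(config$traits)
    M <- animal_abundance(filtered)
    profile <- spearman_profile(M, traits)
    write.table(profile, assoc_files$correlations, sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (length(consensus) >= 2L) {
      nul <- mean_correlation_null(M[consensus, , drop = FALSE], traits,
                                   n_perm = config$n_perm_corr,
                                   seed = seeds$associate)
      cmp <- mean_abs_corr_compare(profile, consensus)
      orr <- correlation_odds_ratio(profile, consensus,
                                    alpha = config$alpha)
      summ <- merge(merge(nul$summary, cmp, by = "index", all = TRUE),
                    orr, by = "index", all = TRUE)
      write.table(summ, assoc_files$summary, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      .log_stage("associate", "indices tested: ", nrow(summ))
    } else {
      writeLines("index", assoc_files$summary)
      .log_stage("associate", "fewer than 2 consensus OTUs; summary empty")
    }
    th <- trait_heritability(traits, a)
    write.table(th, assoc_files$traits_h2, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else .log_stage("associate", "outputs exist, skipped")
  manifest$stages$associate <- assoc_files

  # record everything relative to out_dir so identically-seeded runs are
  # byte-identical wherever they land
  rel <- function(p) if (is.character(p)) sub("^/", "",
    sub(normalizePath(out_dir), "", suppressWarnings(normalizePath(p, mustWork = FALSE)),
        fixed = TRUE)) else p
  all_files <- unlist(manifest$stages, use.names = FALSE)
  manifest$files <- data.frame(
    path = unname(vapply(all_files, rel, "")),
    md5 = unname(tools::md5sum(all_files)), stringsAsFactors = FALSE,
    row.names = NULL)
  manifest$stages <- lapply(manifest$stages, function(s) lapply(s, rel))
  for (f in c("ped", "map", "otu_table", "fasta", "traits"))
    manifest$config[[f]] <- rel(config[[f]])
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}
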