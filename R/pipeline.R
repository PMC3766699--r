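#' Default pipeline configuration
#'
#' One configuration object drives the whole analysis; every stage's
#' parameters have a config twin so that a run is reproducible from the
#' resolved configuration plus the seed alone.
#'
#' @param seed global seed; all stage seeds derive from it.
#' @param cohort named list of [cohort_config()] overrides.
#' @param preprocess list: `min_detected`, `detection_floor`,
#'   `drop_fraction`, `signal_floor`, `fc_threshold`.
#' @param sam list: `n_permutations`, `fdr_target`, `delta_resolution`.
#' @param dem list: `fc_threshold` (log2), `background`.
#' @param support list: `q_max`, `direction`, `method`.
#' @param network list: `top_gene_fraction`, `q_max`.
#' @param pathways list: `alpha`, `direction`.
#' @param survival list: `family_alpha`.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = list(),
                            preprocess = list(),
                            sam = list(),
                            dem = list(),
                            support = list(),
                            network = list(),
                            pathways = list(),
                            survival = list()) {
  merge_over <- function(defaults, over) {
    for (nm in names(over)) defaults[[nm]] <- over[[nm]]
    defaults
  }
  cfg <- list(
    seed = as.integer(seed),
    cohort = cohort,
    preprocess = merge_over(list(min_detected = 20, detection_floor = 1.0,
                                 drop_fraction = 0.30, signal_floor = 5.0,
                                 fc_threshold = 1.0), preprocess),
    sam = merge_over(list(n_permutations = 200L, fdr_target = 0.01,
                          delta_resolution = 100L), sam),
    dem = merge_over(list(fc_threshold = 3.0, background = 5.0), dem),
    support = merge_over(list(q_max = 0.01, direction = "negative",
                              method = "bh"), support),
    network = merge_over(list(top_gene_fraction = 0.75, q_max = 0.05), network),
    pathways = merge_over(list(alpha = 0.05, direction = "two_way"), pathways),
    survival = merge_over(list(family_alpha = 0.05), survival))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Stages, in dependency order: simulate, preprocess, differential
#' expression (SAM), target support, DEM network induction, mixed-network
#' circuit enumeration, pathway perturbation, survival screening. Every
#' stage writes its outputs under `outdir` and contributes row counts to a
#' machine-readable report (`report.json`) that also records stage
#' parameters, input file hashes, and — since the cohort is synthetic with
#' known ground truth — recovery metrics per stage. A rerun with the same
#' configuration and seed reproduces every output byte for byte.
#'
#' @param config a [pipeline_config()], or a path readable by
#'   [read_pipeline_config()].
#' @param outdir output directory (created if missing).
#' @return The report, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sub <- function(d) {
    p <- file.path(outdir, d)
    dir.create(p, showWarnings = FALSE)
    p
  }
  report <- list(seed = config$seed, parameters = config[-1])

  ## ---- simulate ------------------------------------------------------------
  ccfg <- do.call(cohort_config, c(list(seed = config$seed), config$cohort))
  cohort <- generate_cohort(ccfg)
  predictions <- generate_target_predictions(cohort$truth, ccfg)
  interactions <- generate_tf_layer(cohort$truth, ccfg)
  sets <- generate_gene_sets(cohort$truth, ccfg)
  surv_records <- generate_survival(cohort$truth, ccfg)
  ind <- sub("inputs")
  write_expression_matrix(cohort$mirna, file.path(ind, "mirna.tsv"))
  write_expression_matrix(cohort$gene, file.path(ind, "gene.tsv"))
  write_sample_sheet(cohort$sheet, file.path(ind, "samples.tsv"))
  write_target_predictions(predictions, file.path(ind, "predictions.tsv"))
  write_interactions(interactions, file.path(ind, "interactions.tsv"))
  write_gene_sets(sets, file.path(ind, "gene_sets.gmt"))
  write_survival(surv_records, file.path(ind, "survival.tsv"))
  truth <- cohort$truth
  report$simulate <- list(
    n_mirnas = nrow(cohort$mirna), n_genes = nrow(cohort$gene),
    n_mirna_samples = ncol(cohort$mirna), n_gene_samples = ncol(cohort$gene),
    n_matched_samples = length(match_samples(cohort$mirna, cohort$gene)),
    n_predictions = nrow(predictions), n_interactions = nrow(interactions),
    n_clipped = as.list(truth$clipped))

  ## ---- preprocess ----------------------------------------------------------
  pp <- config$preprocess
  mirna_f <- filter_mirnas_by_detection(cohort$mirna, cohort$sheet,
                                        min_detected = pp$min_detected,
                                        detection_floor = pp$detection_floor)
  mirna_f <- filter_by_mean_signal(mirna_f, floor = pp$signal_floor)
  gene_f <- filter_genes_by_variability(cohort$gene, pp$drop_fraction)
  ppd <- sub("preprocess")
  write_expression_matrix(mirna_f, file.path(ppd, "mirna_filtered.tsv"))
  write_expression_matrix(gene_f, file.path(ppd, "gene_filtered.tsv"))
  trans_m <- transition_pattern_counts(mirna_f, cohort$sheet, pp$fc_threshold)
  trans_g <- transition_pattern_counts(gene_f, cohort$sheet, pp$fc_threshold)
  write_tsv(cbind(assay = c("miRNA", "miRNA", "gene", "gene"),
                  rbind(trans_m, trans_g)),
            file.path(ppd, "transition_patterns.tsv"))
  clus_m <- cluster_samples(mirna_f)
  clus_g <- cluster_samples(gene_f)
  report$preprocess <- list(
    n_mirnas_after_detection = nrow(filter_mirnas_by_detection(
      cohort$mirna, cohort$sheet, min_detected = pp$min_detected,
      detection_floor = pp$detection_floor)),
    n_mirnas_after_floor = nrow(mirna_f),
    n_genes_after_variability = nrow(gene_f),
    pairing_fraction_mirna = patient_pairing_score(clus_m, cohort$sheet),
    pairing_fraction_gene = patient_pairing_score(clus_g, cohort$sheet))

  ## ---- differential expression --------------------------------------------
  sam_cfg <- function(off) sam_config(design = "unpaired",
                                      n_permutations = config$sam$n_permutations,
                                      fdr_target = config$sam$fdr_target,
                                      delta_resolution = config$sam$delta_resolution,
                                      seed = config$seed + off)
  de <- sub("diffexp")
  sam_tvn <- sam_fdr(mirna_f, cohort$sheet, c("T", "N"), sam_cfg(11L))
  sam_mvt <- sam_fdr(mirna_f, cohort$sheet, c("M", "T"), sam_cfg(12L))
  sam_gene <- sam_fdr(gene_f, cohort$sheet, c("T", "N"), sam_cfg(13L))
  dems_tvn <- select_dems(sam_tvn, config$dem$fc_threshold, config$dem$background)
  dems_mvt <- select_dems(sam_mvt, config$dem$fc_threshold, config$dem$background)
  degs <- sam_gene$results[sam_gene$results$called, , drop = FALSE]
  write_tsv(sam_tvn$results, file.path(de, "sam_mirna_TvN.tsv"))
  write_tsv(sam_mvt$results, file.path(de, "sam_mirna_MvT.tsv"))
  write_tsv(sam_gene$results, file.path(de, "sam_gene_TvN.tsv"))
  write_tsv(sam_tvn$delta_table, file.path(de, "delta_mirna_TvN.tsv"))
  write_tsv(dems_tvn, file.path(de, "dems_TvN.tsv"))
  write_tsv(dems_mvt, file.path(de, "dems_MvT.tsv"))
  write_tsv(degs, file.path(de, "degs_TvN.tsv"))
  planted_tvn <- truth$dems$feature_id[truth$dems$contrast == "TvN"]
  report$diffexp <- list(
    n_called_mirna_TvN = sum(sam_tvn$results$called),
    n_called_mirna_MvT = sum(sam_mvt$results$called),
    n_dems_TvN = nrow(dems_tvn), n_dems_MvT = nrow(dems_mvt),
    n_degs_TvN = nrow(degs),
    dem_recovery_TvN = if (length(planted_tvn))
      mean(planted_tvn %in% sam_tvn$results$feature_id[sam_tvn$results$called])
    else NA)

  ## ---- target support ------------------------------------------------------
  sup <- config$support
  relations <- support_targets(mirna_f, cohort$gene, predictions,
                               sheet = cohort$sheet, q_max = sup$q_max,
                               direction = sup$direction, method = sup$method)
  sud <- sub("support")
  write_tsv(relations, file.path(sud, "relations.tsv"))
  summ <- summarize_support(relations)
  write_tsv(data.frame(metric = c("n_relations", "n_mirnas", "n_genes",
                                  "mean_targets_per_mirna", "conserved_fraction"),
                       value = c(summ$n_relations, summ$n_mirnas, summ$n_genes,
                                 summ$targets_per_mirna["mean"],
                                 summ$conserved_fraction)),
            file.path(sud, "summary.tsv"))
  planted_keys <- paste(truth$repressions$mirna_id, truth$repressions$gene_id)
  got_keys <- paste(relations$mirna_id, relations$gene_id)
  testable <- truth$repressions$mirna_id %in% rownames(mirna_f)
  report$support <- list(
    n_tested = attr(relations, "n_tested"), n_relations = nrow(relations),
    n_mirnas = summ$n_mirnas, n_genes = summ$n_genes,
    realized_r_cut = attr(relations, "r_cut"),
    repression_recovery = if (any(testable))
      mean(planted_keys[testable] %in% got_keys) else NA)

  ## ---- DEM network ---------------------------------------------------------
  ned <- sub("network")
  net_tvn <- induce_dem_network(relations, dems_tvn, degs)
  comps <- network_components(net_tvn)
  write_network(net_tvn, file.path(ned, "network_TvN"))
  write_tsv(data.frame(component = rep(seq_along(comps),
                                       vapply(comps, length, 1L)),
                       node = unlist(comps)),
            file.path(ned, "components_TvN.tsv"))
  report$network <- list(
    n_nodes = nrow(net_tvn$nodes), n_edges = nrow(net_tvn$edges),
    n_components = length(comps),
    n_deg_targets = sum(net_tvn$nodes$is_deg))

  ## ---- mixed network and circuits -----------------------------------------
  cid <- sub("circuits")
  all_dems <- rbind(dems_tvn, dems_mvt)
  mixed <- build_mixed_network(mirna_f, cohort$gene, cohort$sheet, relations,
                               interactions, dems = all_dems,
                               top_gene_fraction = config$network$top_gene_fraction,
                               q_max = config$network$q_max)
  circuits <- enumerate_circuits(mixed)
  write_network(mixed, file.path(cid, "mixed_network"))
  write_tsv(circuits, file.path(cid, "circuits.tsv"))
  truth_keys <- paste(truth$circuits$circuit_type, truth$circuits$tf,
                      truth$circuits$mirna, truth$circuits$gene)
  found_keys <- paste(circuits$circuit_type, circuits$tf, circuits$mirna,
                      circuits$gene)
  report$circuits <- list(
    n_mixed_nodes = nrow(mixed$nodes), n_mixed_edges = nrow(mixed$edges),
    n_circuits = nrow(circuits),
    circuit_recovery = if (length(truth_keys)) mean(truth_keys %in% found_keys)
    else NA)

  ## ---- pathways ------------------------------------------------------------
  pad <- sub("pathways")
  gene_stats <- gene_level_statistics(cohort$gene, cohort$sheet, c("T", "N"))
  path_a <- enrich_pathways(relations, all_dems, degs, sets, gene_stats,
                            strategy = "A", direction = config$pathways$direction,
                            alpha = config$pathways$alpha)
  path_b <- enrich_pathways(relations, all_dems, degs, sets, gene_stats,
                            strategy = "B", direction = config$pathways$direction,
                            alpha = config$pathways$alpha)
  write_tsv(path_a, file.path(pad, "pathways_strategy_A.tsv"))
  write_tsv(path_b, file.path(pad, "pathways_strategy_B.tsv"))
  report$pathways <- list(
    n_tested_A = nrow(path_a), n_significant_A = sum(path_a$significant),
    n_tested_B = nrow(path_b), n_significant_B = sum(path_b$significant),
    planted_set_significant_A = isTRUE(
      path_a$significant[match("planted_perturbed", path_a$set_name)]))

  ## ---- survival ------------------------------------------------------------
  svd <- sub("survival")
  screen_list <- intersect(names(truth$survival_beta), colnames(surv_records))
  fits <- screen_mirnas(surv_records, levels = NULL, mirnas = screen_list,
                        family_alpha = config$survival$family_alpha)
  write_tsv(fits, file.path(svd, "cox_screen.tsv"))
  if (nrow(fits)) {
    top <- fits$covariate_name[1]
    km <- km_curve(surv_records, dichotomize_median(surv_records[[top]]))
    write_tsv(km$curves, file.path(svd, paste0("km_", top, ".tsv")))
    write_tsv(data.frame(group = names(km$median), median = unname(km$median)),
              file.path(svd, paste0("km_", top, "_median.tsv")))
  }
  planted_surv <- names(truth$survival_beta)[truth$survival_beta != 0]
  report$survival <- list(
    n_screened = nrow(fits), per_test_alpha = attr(fits, "per_test_alpha"),
    n_significant = sum(fits$significant),
    top_mirna = if (nrow(fits)) fits$covariate_name[1] else NA,
    top_is_planted = if (length(planted_surv) && nrow(fits))
      fits$covariate_name[1] %in% planted_surv else NA)

  ## ---- report --------------------------------------------------------------
  inputs <- list.files(ind, full.names = TRUE)
  report$input_hashes <- as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                                 basename(inputs)))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(config), file.path(outdir, "config_resolved.yaml"))
  invisible(report)
}
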