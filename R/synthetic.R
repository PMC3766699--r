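#' Configuration for the synthetic matched cohort
#'
#' Defines the conditions the generator emulates: a three-class cohort
#' (normal mucosa N, primary tumor T, liver metastasis M) with partial
#' per-patient matching across a miRNA assay and a gene assay, class-level
#' differential effects concentrated in the T-vs-N transition (and carried
#' into M), planted linear miRNA-to-target repressions, mixed miRNA-TF
#' circuits, and proportional-hazards survival effects.
#'
#' Defaults mirror the reference cohort structure: 46 patients, per-class
#' sample counts 23/31/24 (miRNA assay) and 23/30/27 (gene assay) with 77
#' samples assayed on both platforms, and log2 signal confined to \[0, 15\].
#' Baseline per-feature means are drawn uniformly on \[3, 9\] so that a large
#' fraction of miRNAs falls below the conventional signal floor of 5;
#' planted-effect features draw their baselines above the floor, reflecting
#' that the analysis restricts itself to well-expressed miRNAs.
#'
#' @param seed integer; fixes every source of randomness.
#' @param n_patients number of patients.
#' @param mirna_class_counts,gene_class_counts named integer vectors
#'   (N, T, M) of per-assay sample counts.
#' @param n_mirnas,n_genes feature counts (genes exclude appended TF rows).
#' @param n_planted_dems named vector: planted differential miRNAs per
#'   contrast (`TvN` effects are applied to T and M alike; `MvT` to M only).
#' @param dem_effect absolute planted miRNA effect, log2 units (signs
#'   alternate up/down).
#' @param n_planted_degs,deg_effect planted differential genes for the
#'   T-vs-N contrast and their absolute log2 effect.
#' @param n_planted_repressions number of planted miRNA-target pairs.
#' @param repression_slope slope `b` (log2 gene per log2 miRNA): target =
#'   baseline − b * (miRNA − mean(miRNA)) + noise.
#' @param repression_noise_sd Gaussian noise sd of the repression relation.
#' @param n_decoy_predictions decoy (non-interacting) prediction pairs.
#' @param conserved_fraction_planted,conserved_fraction_decoy probability a
#'   planted / decoy prediction is flagged as conserved.
#' @param n_planted_circuits named vector (`TF_driven`, `miRNA_driven`).
#' @param n_decoy_tfs,n_decoy_tf_edges decoy TF rows and decoy TF edges.
#' @param patient_effect_sd sd of the per-feature patient random effect
#'   shared by the T and M samples of a patient (drives per-patient pairing
#'   in clustering; a free parameter of the generator).
#' @param noise_sd per-sample Gaussian noise sd (log2 units).
#' @param baseline_range,planted_baseline_range uniform ranges for feature
#'   baseline means.
#' @param signal_range values are clipped into this range after generation;
#'   clipping events are counted in the ground truth.
#' @param survival_beta log-hazard per unit (log2) miRNA level for the
#'   planted prognostic miRNA (the first M-vs-T differential miRNA).
#' @param survival_baseline_hazard baseline hazard (events per month).
#' @param censoring_rate target fraction of censored records.
#' @param n_survival number of survival records (default: one per patient).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_patients = 46L,
                          mirna_class_counts = c(N = 23L, T = 31L, M = 24L),
                          gene_class_counts = c(N = 23L, T = 30L, M = 27L),
                          n_mirnas = 300L,
                          n_genes = 2000L,
                          n_planted_dems = c(TvN = 25L, MvT = 5L),
                          dem_effect = 4,
                          n_planted_degs = 100L,
                          deg_effect = 2,
                          n_planted_repressions = 50L,
                          repression_slope = 1,
                          repression_noise_sd = 0.5,
                          n_decoy_predictions = 2000L,
                          conserved_fraction_planted = 0.87,
                          conserved_fraction_decoy = 0.25,
                          n_planted_circuits = c(TF_driven = 3L, miRNA_driven = 3L),
                          n_decoy_tfs = 14L,
                          n_decoy_tf_edges = 100L,
                          patient_effect_sd = 1,
                          noise_sd = 1,
                          baseline_range = c(3, 9),
                          planted_baseline_range = c(5.5, 9),
                          signal_range = c(0, 15),
                          survival_beta = 0.4,
                          survival_baseline_hazard = 0.02,
                          censoring_rate = 0.3,
                          n_survival = NULL) {
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              mirna_class_counts = mirna_class_counts,
              gene_class_counts = gene_class_counts,
              n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
              n_planted_dems = n_planted_dems, dem_effect = dem_effect,
              n_planted_degs = as.integer(n_planted_degs), deg_effect = deg_effect,
              n_planted_repressions = as.integer(n_planted_repressions),
              repression_slope = repression_slope,
              repression_noise_sd = repression_noise_sd,
              n_decoy_predictions = as.integer(n_decoy_predictions),
              conserved_fraction_planted = conserved_fraction_planted,
              conserved_fraction_decoy = conserved_fraction_decoy,
              n_planted_circuits = n_planted_circuits,
              n_decoy_tfs = as.integer(n_decoy_tfs),
              n_decoy_tf_edges = as.integer(n_decoy_tf_edges),
              patient_effect_sd = patient_effect_sd, noise_sd = noise_sd,
              baseline_range = baseline_range,
              planted_baseline_range = planted_baseline_range,
              signal_range = signal_range,
              survival_beta = survival_beta,
              survival_baseline_hazard = survival_baseline_hazard,
              censoring_rate = censoring_rate,
              n_survival = if (is.null(n_survival)) as.integer(n_patients) else as.integer(n_survival))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  counts <- c(cfg$n_patients, cfg$n_mirnas, cfg$n_genes, cfg$n_planted_dems,
              cfg$n_planted_degs, cfg$n_planted_repressions,
              cfg$n_decoy_predictions, cfg$n_planted_circuits,
              cfg$n_decoy_tfs, cfg$n_decoy_tf_edges, cfg$n_survival,
              cfg$mirna_class_counts, cfg$gene_class_counts)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (!all(c("N", "T", "M") %in% names(cfg$mirna_class_counts)) ||
      !all(c("N", "T", "M") %in% names(cfg$gene_class_counts))) {
    stop("class counts must be named N, T, M")
  }
  n_circ <- sum(cfg$n_planted_circuits)
  n_planted_mirnas <- sum(cfg$n_planted_dems) + cfg$n_planted_repressions
  if (n_planted_mirnas > cfg$n_mirnas) {
    stop("more planted miRNA features than n_mirnas")
  }
  if (n_circ > sum(cfg$n_planted_dems)) {
    stop("planted circuits require at least as many planted differential miRNAs")
  }
  if (cfg$n_planted_repressions + cfg$n_planted_degs + n_circ > cfg$n_genes) {
    stop("more planted gene features than n_genes")
  }
  if (cfg$censoring_rate < 0 || cfg$censoring_rate > 1) {
    stop("censoring_rate must lie in [0, 1]")
  }
  if (cfg$dem_effect < 0 || cfg$deg_effect < 0) stop("effect sizes are absolute (>= 0)")
  invisible(cfg)
}

# Reference match design: which tissue samples each patient contributes to
# each assay. Mirrors a partially matched cohort: 8 N/T/M triplets, N/T and
# T/M pairs, a few N/M pairs, and unmatched singletons; one T sample is
# miRNA-only and three M samples are gene-only so the two assays share 77
# of their samples.
cohort_sample_design <- function(cfg) {
  pid <- sprintf("P%02d", seq_len(max(cfg$n_patients, 1L)))
  mk <- function(p, tissues) {
    data.frame(sample_id = paste(p, tissues, sep = "_"), patient_id = p,
               tissue = tissues, stringsAsFactors = FALSE)
  }
  default_counts <- identical(as.integer(cfg$mirna_class_counts[c("N", "T", "M")]),
                              c(23L, 31L, 24L)) &&
    identical(as.integer(cfg$gene_class_counts[c("N", "T", "M")]),
              c(23L, 30L, 27L)) && cfg$n_patients >= 46L
  if (default_counts) {
    rows <- list()
    for (i in 1:8)   rows[[length(rows) + 1]] <- mk(pid[i], c("N", "T", "M"))
    for (i in 9:15)  rows[[length(rows) + 1]] <- mk(pid[i], c("N", "T"))
    for (i in 16:23) rows[[length(rows) + 1]] <- mk(pid[i], c("T", "M"))
    for (i in 24:25) rows[[length(rows) + 1]] <- mk(pid[i], c("N", "M"))
    for (i in 26:31) rows[[length(rows) + 1]] <- mk(pid[i], "N")
    for (i in 32:39) rows[[length(rows) + 1]] <- mk(pid[i], "T")
    for (i in 40:45) rows[[length(rows) + 1]] <- mk(pid[i], "M")
    mirna_sheet <- do.call(rbind, rows)
    gene_only <- do.call(rbind, list(mk(pid[9], "M"), mk(pid[10], "M"), mk(pid[46], "M")))
    mirna_samples <- mirna_sheet$sample_id
    gene_samples <- c(setdiff(mirna_samples, "P39_T"), gene_only$sample_id)
    full <- rbind(mirna_sheet, gene_only)
  } else {
    # generic greedy design: triplets while every class has samples left,
    # then T-M and N-T pairs, then singletons; both assays fully overlap
    build <- function(counts, pid) {
      rem <- counts[c("N", "T", "M")]
      rows <- list(); i <- 0
      while (all(rem > 0)) { i <- i + 1; rows[[i]] <- mk(pid[i], c("N", "T", "M")); rem <- rem - 1 }
      while (rem["T"] > 0 && rem["M"] > 0) { i <- i + 1; rows[[i]] <- mk(pid[i], c("T", "M")); rem[c("T", "M")] <- rem[c("T", "M")] - 1 }
      while (rem["N"] > 0 && rem["T"] > 0) { i <- i + 1; rows[[i]] <- mk(pid[i], c("N", "T")); rem[c("N", "T")] <- rem[c("N", "T")] - 1 }
      for (cl in c("N", "T", "M")) while (rem[cl] > 0) { i <- i + 1; rows[[i]] <- mk(pid[i], cl); rem[cl] <- rem[cl] - 1 }
      do.call(rbind, rows)
    }
    m_sheet <- build(cfg$mirna_class_counts, pid)
    g_sheet <- build(cfg$gene_class_counts, pid)
    full <- unique(rbind(m_sheet, g_sheet))
    mirna_samples <- m_sheet$sample_id
    gene_samples <- g_sheet$sample_id
  }
  sheet <- sample_sheet(full$sample_id, full$patient_id, full$tissue)
  list(sheet = sheet, mirna_samples = mirna_samples, gene_samples = gene_samples)
}

# baseline + class effects + patient effect + noise for one feature block;
# effects: numeric vector per feature (0 if not planted), applied per contrast
simulate_feature_block <- function(n_feat, ids, baselines, sheet,
                                   tvn_effect, mvt_effect, cfg) {
  n_samp <- nrow(sheet)
  vals <- matrix(stats::rnorm(n_feat * n_samp, sd = cfg$noise_sd),
                 nrow = n_feat, dimnames = list(ids, sheet$sample_id))
  vals <- vals + baselines
  is_t <- sheet$tissue == "T"
  is_m <- sheet$tissue == "M"
  # T-vs-N effects manifest in the primary tumor and persist in metastasis
  vals[, is_t | is_m] <- vals[, is_t | is_m] + tvn_effect
  vals[, is_m] <- vals[, is_m] + mvt_effect
  # patient random effect: a per-feature patient-specific profile shared by
  # the T and M samples of that patient (drives tumor/metastasis pairing)
  if (cfg$patient_effect_sd > 0) {
    pts <- unique(sheet$patient_id[is_t | is_m])
    eff <- matrix(stats::rnorm(n_feat * length(pts), sd = cfg$patient_effect_sd),
                  nrow = n_feat, dimnames = list(NULL, pts))
    tm_idx <- which(is_t | is_m)
    vals[, tm_idx] <- vals[, tm_idx] + eff[, sheet$patient_id[tm_idx], drop = FALSE]
  }
  vals
}

#' Generate a synthetic matched N/T/M cohort with planted ground truth
#'
#' Produces a miRNA and a gene log2 expression matrix over a partially
#' matched sample design, a sample sheet, and a `cohort_truth` object
#' recording every planted effect so downstream recovery can be measured.
#' Planted T-vs-N effects are applied to T and M samples alike (expression
#' changes manifest early and persist in metastasis); planted repressions set
#' each target to `baseline - b * (miRNA - mean(miRNA)) + noise` sample-wise;
#' planted circuits wire a TF expression row (appended to the gene matrix)
#' to a differential miRNA and a target gene. All values are clipped into
#' `signal_range`; clip counts are reported in the truth object.
#'
#' @param config a [cohort_config()].
#' @return List with elements `mirna` and `gene` (expression matrices),
#'   `sheet` (sample sheet over the union of assayed samples) and `truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  cfg <- config
  set.seed(cfg$seed)
  design <- cohort_sample_design(cfg)
  sheet <- design$sheet

  ## ---- feature bookkeeping -------------------------------------------------
  mirna_ids <- sprintf("miR_%03d", seq_len(cfg$n_mirnas))
  gene_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  n_tvn <- unname(cfg$n_planted_dems["TvN"]); if (is.na(n_tvn)) n_tvn <- 0L
  n_mvt <- unname(cfg$n_planted_dems["MvT"]); if (is.na(n_mvt)) n_mvt <- 0L
  dem_tvn <- mirna_ids[seq_len(n_tvn)]
  dem_mvt <- mirna_ids[n_tvn + seq_len(n_mvt)]
  # a good share of repressions hang off differential miRNAs (round-robin,
  # several targets per DEM) so the induced DEM-centred network is populated;
  # the rest use dedicated stable miRNAs
  n_rep_on_dem <- min(3L * n_tvn, cfg$n_planted_repressions,
                      max(0L, cfg$n_planted_repressions - 20L))
  rep_mirnas <- c(
    if (n_rep_on_dem > 0) rep_len(dem_tvn, n_rep_on_dem),
    mirna_ids[n_tvn + n_mvt +
                seq_len(cfg$n_planted_repressions - n_rep_on_dem)])
  n_ci <- unname(cfg$n_planted_circuits["TF_driven"]); if (is.na(n_ci)) n_ci <- 0L
  n_cii <- unname(cfg$n_planted_circuits["miRNA_driven"]); if (is.na(n_cii)) n_cii <- 0L
  circ_mirnas <- c(dem_tvn, dem_mvt)[seq_len(n_ci + n_cii)]

  deg_genes <- gene_ids[seq_len(cfg$n_planted_degs)]
  rep_genes <- gene_ids[cfg$n_planted_degs + seq_len(cfg$n_planted_repressions)]
  circ_genes <- gene_ids[cfg$n_planted_degs + cfg$n_planted_repressions +
                           seq_len(n_ci + n_cii)]
  tf_ids <- sprintf("TF_%02d", seq_len(n_ci + n_cii + cfg$n_decoy_tfs))
  circ_tfs <- tf_ids[seq_len(n_ci + n_cii)]

  ## ---- miRNA matrix over every sample (assay columns selected at the end) --
  planted_mirna <- mirna_ids %in% c(dem_tvn, dem_mvt, rep_mirnas)
  mu_m <- stats::runif(cfg$n_mirnas, cfg$baseline_range[1], cfg$baseline_range[2])
  mu_m[planted_mirna] <- stats::runif(sum(planted_mirna),
                                      cfg$planted_baseline_range[1],
                                      cfg$planted_baseline_range[2])
  eff_tvn <- numeric(cfg$n_mirnas)
  eff_tvn[match(dem_tvn, mirna_ids)] <- cfg$dem_effect * rep_len(c(1, -1), n_tvn)
  eff_mvt <- numeric(cfg$n_mirnas)
  eff_mvt[match(dem_mvt, mirna_ids)] <- cfg$dem_effect * rep_len(c(1, -1), n_mvt)
  M_full <- simulate_feature_block(cfg$n_mirnas, mirna_ids, mu_m, sheet,
                                   eff_tvn, eff_mvt, cfg)

  ## ---- gene matrix ---------------------------------------------------------
  mu_g <- stats::runif(cfg$n_genes, cfg$baseline_range[1], cfg$baseline_range[2])
  planted_gene <- gene_ids %in% c(rep_genes, circ_genes)
  mu_g[planted_gene] <- stats::runif(sum(planted_gene),
                                     cfg$planted_baseline_range[1],
                                     cfg$planted_baseline_range[2])
  geff_tvn <- numeric(cfg$n_genes)
  geff_tvn[match(deg_genes, gene_ids)] <- cfg$deg_effect * rep_len(c(1, -1), cfg$n_planted_degs)
  G_full <- simulate_feature_block(cfg$n_genes, gene_ids, mu_g, sheet,
                                   geff_tvn, numeric(cfg$n_genes), cfg)

  # planted repressions overwrite their target rows: linear in log2 space.
  # Repressions hosted by up-modulated DEMs get the full slope (their targets
  # shift coherently down, the detectable perturbed gene set); those hosted
  # by down-modulated DEMs get a weaker slope, diluting the target universe
  # the way partially repressed targets do in real data.
  b <- cfg$repression_slope
  host_eff <- eff_tvn[match(rep_mirnas, mirna_ids)]
  rep_slopes <- ifelse(host_eff < 0, 0.35 * b, b)
  for (k in seq_len(cfg$n_planted_repressions)) {
    m <- M_full[rep_mirnas[k], ]
    G_full[rep_genes[k], ] <- mu_g[match(rep_genes[k], gene_ids)] -
      rep_slopes[k] * (m - mean(m)) +
      stats::rnorm(ncol(G_full), sd = cfg$repression_noise_sd)
  }

  ## ---- TF rows and circuits ------------------------------------------------
  mu_tf <- stats::runif(length(tf_ids), cfg$planted_baseline_range[1],
                        cfg$planted_baseline_range[2])
  TF_full <- matrix(stats::rnorm(length(tf_ids) * nrow(sheet), sd = cfg$noise_sd),
                    nrow = length(tf_ids), ncol = nrow(sheet),
                    dimnames = list(tf_ids, sheet$sample_id)) + mu_tf
  circuits <- data.frame(circuit_type = character(), tf = character(),
                         mirna = character(), gene = character(),
                         stringsAsFactors = FALSE)
  circ_sd <- 0.4
  for (k in seq_len(n_ci + n_cii)) {
    type <- if (k <= n_ci) "TF_driven" else "miRNA_driven"
    m_id <- circ_mirnas[k]; t_id <- circ_tfs[k]; g_id <- circ_genes[k]
    m <- M_full[m_id, ]; mc <- m - mean(m)
    if (type == "TF_driven") {
      # TF drives both the miRNA and the gene; the miRNA represses the gene
      TF_full[t_id, ] <- mu_tf[k] + 0.7 * mc + stats::rnorm(length(m), sd = circ_sd)
      G_full[g_id, ] <- mu_g[match(g_id, gene_ids)] - 0.8 * mc +
        stats::rnorm(length(m), sd = circ_sd)
    } else {
      # miRNA represses both the TF and the TF's target gene
      TF_full[t_id, ] <- mu_tf[k] - 0.7 * mc + stats::rnorm(length(m), sd = circ_sd)
      tc <- TF_full[t_id, ] - mean(TF_full[t_id, ])
      G_full[g_id, ] <- mu_g[match(g_id, gene_ids)] + 0.8 * tc +
        stats::rnorm(length(m), sd = circ_sd)
    }
    circuits <- rbind(circuits, data.frame(circuit_type = type, tf = t_id,
                                           mirna = m_id, gene = g_id,
                                           stringsAsFactors = FALSE))
  }
  G_full <- rbind(G_full, TF_full)

  ## ---- clip to the stated signal scale ------------------------------------
  lo <- cfg$signal_range[1]; hi <- cfg$signal_range[2]
  clipped <- c(mirna = sum(M_full < lo | M_full > hi),
               gene = sum(G_full < lo | G_full > hi))
  M_full[M_full < lo] <- lo; M_full[M_full > hi] <- hi
  G_full[G_full < lo] <- lo; G_full[G_full > hi] <- hi

  mirna <- expression_matrix(M_full[, design$mirna_samples, drop = FALSE], "miRNA")
  gene <- expression_matrix(G_full[, design$gene_samples, drop = FALSE], "gene")

  matched <- intersect(design$mirna_samples, design$gene_samples)
  sd_m <- apply(M_full[rep_mirnas, matched, drop = FALSE], 1, stats::sd)
  repressions <- data.frame(
    mirna_id = rep_mirnas, gene_id = rep_genes, slope = rep_slopes,
    noise_sd = rep(cfg$repression_noise_sd, length(rep_mirnas)),
    analytic_r = -rep_slopes * sd_m /
      sqrt(rep_slopes^2 * sd_m^2 + cfg$repression_noise_sd^2),
    stringsAsFactors = FALSE)

  dems <- rbind(
    data.frame(feature_id = dem_tvn, contrast = rep("TvN", length(dem_tvn)),
               effect = eff_tvn[match(dem_tvn, mirna_ids)], stringsAsFactors = FALSE),
    data.frame(feature_id = dem_mvt, contrast = rep("MvT", length(dem_mvt)),
               effect = eff_mvt[match(dem_mvt, mirna_ids)], stringsAsFactors = FALSE))
  degs <- data.frame(feature_id = deg_genes,
                     contrast = rep("TvN", length(deg_genes)),
                     effect = geff_tvn[match(deg_genes, gene_ids)],
                     stringsAsFactors = FALSE)

  surv_mirnas <- c(dem_mvt, dem_tvn)
  surv_mirnas <- surv_mirnas[seq_len(min(26L, length(surv_mirnas)))]
  survival_beta <- stats::setNames(numeric(length(surv_mirnas)), surv_mirnas)
  if (length(dem_mvt)) survival_beta[dem_mvt[1]] <- cfg$survival_beta

  truth <- structure(list(
    config = cfg, dems = dems, degs = degs, repressions = repressions,
    circuits = circuits, tf_ids = tf_ids, circuit_tfs = circ_tfs,
    survival_beta = survival_beta, clipped = clipped,
    mirna_ids = mirna_ids, gene_ids = gene_ids,
    matched_samples = matched), class = "cohort_truth")

  list(mirna = mirna, gene = gene, sheet = sheet, truth = truth)
}

#' Generate a target-prediction table containing the planted truth
#'
#' Every planted repression and circuit miRNA-target pair appears as a
#' prediction; `n_decoy_predictions` additional pairs are sampled among
#' non-interacting (miRNA, gene) combinations. Planted pairs draw more
#' negative miRSVR-style scores than decoys and are conserved with higher
#' probability; the pipeline itself thresholds on correlation support, so
#' scores are descriptive.
#'
#' @param truth a `cohort_truth` from [generate_cohort()].
#' @param config the same [cohort_config()].
#' @return data.frame: mirna_id, gene_id, score, conserved.
#' @export
generate_target_predictions <- function(truth, config = truth$config) {
  set.seed(config$seed + 1L)
  planted <- truth$repressions[, c("mirna_id", "gene_id")]
  # circuit miRNA->gene and miRNA->TF relations are predictions too
  if (nrow(truth$circuits)) {
    planted <- rbind(planted,
                     data.frame(mirna_id = truth$circuits$mirna,
                                gene_id = truth$circuits$gene, stringsAsFactors = FALSE))
    md <- truth$circuits[truth$circuits$circuit_type == "miRNA_driven", ]
    if (nrow(md)) {
      planted <- rbind(planted, data.frame(mirna_id = md$mirna, gene_id = md$tf,
                                           stringsAsFactors = FALSE))
    }
  }
  planted <- unique(planted)
  planted_key <- paste(planted$mirna_id, planted$gene_id)
  # decoys calibrate the support filter's FDR, so they are drawn as genuine
  # null pairs: neither member carries a planted class effect (two features
  # independently shifted in the same contrast would be confounded, not null)
  null_mirnas <- setdiff(truth$mirna_ids,
                         c(truth$dems$feature_id, truth$repressions$mirna_id))
  null_genes <- setdiff(truth$gene_ids,
                        c(truth$degs$feature_id, truth$repressions$gene_id,
                          truth$circuits$gene))
  n_avail <- length(null_mirnas) * length(null_genes)
  if (config$n_decoy_predictions > n_avail) {
    stop("requested more decoy predictions than available non-interacting pairs")
  }
  decoy <- data.frame(mirna_id = character(), gene_id = character())
  if (config$n_decoy_predictions > 0) {
    got <- character(0)
    while (length(got) < config$n_decoy_predictions) {
      need <- config$n_decoy_predictions - length(got)
      cand <- paste(sample(null_mirnas, 2 * need + 10, replace = TRUE),
                    sample(null_genes, 2 * need + 10, replace = TRUE))
      cand <- setdiff(unique(cand), c(planted_key, got))
      got <- c(got, utils::head(cand, need))
    }
    parts <- strsplit(got, " ", fixed = TRUE)
    decoy <- data.frame(mirna_id = vapply(parts, `[`, "", 1),
                        gene_id = vapply(parts, `[`, "", 2), stringsAsFactors = FALSE)
  }
  out <- rbind(
    cbind(planted,
          score = stats::runif(nrow(planted), -1.2, -0.7),
          conserved = stats::runif(nrow(planted)) < config$conserved_fraction_planted),
    cbind(decoy,
          score = stats::runif(nrow(decoy), -0.7, -0.1),
          conserved = stats::runif(nrow(decoy)) < config$conserved_fraction_decoy))
  rownames(out) <- NULL
  out
}

#' Generate the validated TF interaction layer
#'
#' Emits the TF-to-miRNA and TF-to-gene edges realizing each planted circuit,
#' plus decoy edges from decoy TFs to random genes and miRNAs. TF expression
#' rows were already appended to the gene matrix by [generate_cohort()].
#'
#' @inheritParams generate_target_predictions
#' @return Interaction data.frame (regulator_id, target_id, target_kind,
#'   source_label).
#' @export
generate_tf_layer <- function(truth, config = truth$config) {
  set.seed(config$seed + 2L)
  rows <- list()
  for (k in seq_len(nrow(truth$circuits))) {
    ci <- truth$circuits[k, ]
    rows[[length(rows) + 1]] <- data.frame(
      regulator_id = ci$tf, target_id = ci$gene, target_kind = "gene",
      source_label = "planted", stringsAsFactors = FALSE)
    if (ci$circuit_type == "TF_driven") {
      rows[[length(rows) + 1]] <- data.frame(
        regulator_id = ci$tf, target_id = ci$mirna, target_kind = "miRNA",
        source_label = "planted", stringsAsFactors = FALSE)
    }
  }
  planted <- if (length(rows)) do.call(rbind, rows) else
    data.frame(regulator_id = character(), target_id = character(),
               target_kind = character(), source_label = character())
  decoy_tfs <- setdiff(truth$tf_ids, truth$circuit_tfs)
  decoy <- data.frame()
  if (config$n_decoy_tf_edges > 0 && length(decoy_tfs)) {
    n <- config$n_decoy_tf_edges
    kind <- ifelse(stats::runif(n) < 0.7, "gene", "miRNA")
    tgt <- ifelse(kind == "gene",
                  sample(truth$gene_ids, n, replace = TRUE),
                  sample(truth$mirna_ids, n, replace = TRUE))
    decoy <- unique(data.frame(regulator_id = sample(decoy_tfs, n, replace = TRUE),
                               target_id = tgt, target_kind = kind,
                               source_label = "decoy", stringsAsFactors = FALSE))
  }
  out <- rbind(planted, decoy)
  out <- out[!duplicated(paste(out$regulator_id, out$target_id)), ]
  rownames(out) <- NULL
  out
}

#' Generate survival records under an exponential proportional-hazards model
#'
#' Event times are exponential with hazard
#' `h0 * exp(sum_j beta_j * (x_j - 6))` where `x_j` are per-patient log2
#' miRNA levels drawn N(6, 1); censoring times are independent exponentials
#' calibrated so that roughly `censoring_rate` of records are censored.
#'
#' @inheritParams generate_target_predictions
#' @param beta optional named vector of log-hazard coefficients per miRNA;
#'   defaults to `truth$survival_beta`.
#' @return data.frame: patient_id, time (months), event, one covariate
#'   column per screened miRNA.
#' @export
generate_survival <- function(truth, config = truth$config, beta = truth$survival_beta) {
  set.seed(config$seed + 3L)
  n <- config$n_survival
  ids <- sprintf("SP%03d", seq_len(n))
  x <- matrix(stats::rnorm(n * length(beta), mean = 6, sd = 1), nrow = n,
              dimnames = list(NULL, names(beta)))
  lp <- drop(x %*% beta) - sum(beta) * 6
  h0 <- config$survival_baseline_hazard
  t_event <- stats::rexp(n, rate = h0 * exp(lp))
  cr <- config$censoring_rate
  if (cr >= 1) {
    time <- stats::rexp(n, rate = h0)
    event <- rep(0L, n)
  } else if (cr <= 0) {
    time <- t_event
    event <- rep(1L, n)
  } else {
    t_cens <- stats::rexp(n, rate = h0 * cr / (1 - cr))
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  out <- data.frame(patient_id = ids, time = pmax(time, 1e-6), event = event,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(x))
}

#' Generate synthetic gene sets including one planted perturbed set
#'
#' The first set collects planted repression targets (genes that shift with
#' their differential miRNAs and are therefore genuinely perturbed in the
#' T-vs-N contrast); the remaining sets are random draws from the gene
#' universe and serve as nulls.
#'
#' @inheritParams generate_target_predictions
#' @param n_sets total number of sets.
#' @param set_size members per set.
#' @return Named list of gene-ID vectors.
#' @export
generate_gene_sets <- function(truth, config = truth$config,
                               n_sets = 20L, set_size = 25L) {
  set.seed(config$seed + 4L)
  sets <- list()
  up_dems <- truth$dems$feature_id[truth$dems$effect > 0]
  planted <- truth$repressions$gene_id[truth$repressions$mirna_id %in% up_dems]
  if (!length(planted)) {
    planted <- truth$repressions$gene_id[
      truth$repressions$mirna_id %in% truth$dems$feature_id]
  }
  if (!length(planted)) planted <- truth$repressions$gene_id
  sets[["planted_perturbed"]] <- utils::head(planted, set_size)
  for (k in seq_len(max(0L, n_sets - 1L))) {
    sets[[sprintf("null_set_%02d", k)]] <- sample(truth$gene_ids,
                                                  min(set_size, length(truth$gene_ids)))
  }
  sets
}
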