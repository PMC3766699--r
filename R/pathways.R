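#' Per-gene contrast statistics
#'
#' Welch two-sample t statistic per gene between two tissue classes,
#' oriented class a minus class b. These are the gene-level inputs to the
#' set-perturbation test.
#'
#' @param x gene `expr_matrix`.
#' @param sheet [sample_sheet()].
#' @param contrast length-2 character, e.g. `c("T", "N")`.
#' @return Named numeric vector of t statistics.
#' @export
gene_level_statistics <- function(x, sheet, contrast) {
  stopifnot(is_expression_matrix(x))
  tiss <- tissue_of(sheet, colnames(x))
  A <- unclass(x)[, tiss == contrast[1], drop = FALSE]
  B <- unclass(x)[, tiss == contrast[2], drop = FALSE]
  if (ncol(A) < 2 || ncol(B) < 2) stop("each class needs >= 2 samples")
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, stats::var); vb <- apply(B, 1, stats::var)
  se <- sqrt(va / ncol(A) + vb / ncol(B))
  tstat <- (ma - mb) / pmax(se, .Machine$double.eps)
  tstat[se == 0 & ma == mb] <- 0
  tstat
}

#' Two-directional gene-set perturbation test
#'
#' Tests whether a gene set's contrast statistics deviate from the
#' background of all tested genes:
#' `z = (mean_set - mean_all) * sqrt(|S|) / sd_all`, with a one-sided
#' normal p-value for the `up` / `down` directions and a two-sided one for
#' `two_way` (perturbation in either direction counts). Members absent from
#' the statistic universe are dropped and counted; sets with fewer than two
#' present members are flagged untestable.
#'
#' @param gene_stats named numeric vector from [gene_level_statistics()]
#'   (or any per-gene statistic).
#' @param gene_set character vector of member gene IDs.
#' @param direction `"two_way"` (default), `"up"` or `"down"`.
#' @param set_name label carried into the result.
#' @return One-row data.frame: set_name, direction, set_size_tested,
#'   n_absent, z, p, testable.
#' @export
gage_set_test <- function(gene_stats, gene_set, direction = c("two_way", "up", "down"),
                          set_name = NA_character_) {
  direction <- match.arg(direction)
  present <- intersect(unique(gene_set), names(gene_stats))
  n_absent <- length(unique(gene_set)) - length(present)
  if (length(present) < 2) {
    return(data.frame(set_name = set_name, direction = direction,
                      set_size_tested = length(present), n_absent = n_absent,
                      z = NA_real_, p = NA_real_, testable = FALSE,
                      stringsAsFactors = FALSE))
  }
  mu <- mean(gene_stats)
  sdev <- stats::sd(gene_stats)
  z <- if (sdev == 0) 0 else
    (mean(gene_stats[present]) - mu) * sqrt(length(present)) / sdev
  p <- switch(direction,
              up = stats::pnorm(z, lower.tail = FALSE),
              down = stats::pnorm(z),
              two_way = 2 * stats::pnorm(-abs(z)))
  data.frame(set_name = set_name, direction = direction,
             set_size_tested = length(present), n_absent = n_absent,
             z = z, p = p, testable = TRUE, stringsAsFactors = FALSE)
}

#' Pathway perturbation by DEM targets, under two enrichment strategies
#'
#' Strategy `"A"` tests each gene set against the universe of all supported
#' targets of the selected differential miRNAs (pathways enriched in genes
#' targeted by DEMs whose expression shifts in the contrast); strategy
#' `"B"` restricts the universe to targets that are themselves
#' differentially expressed (pathways enriched in DEG targets of DEMs, the
#' more conservative reading). Results at `p < alpha` are flagged
#' significant.
#'
#' @param relations supported relations ([support_targets()]).
#' @param dems DEM table (needs `feature_id`).
#' @param degs DEG table (needs `feature_id`) or character vector.
#' @param sets named list of gene sets ([read_gene_sets()]).
#' @param gene_stats per-gene contrast statistics covering the target genes
#'   ([gene_level_statistics()]).
#' @param strategy `"A"` or `"B"`.
#' @param direction passed to [gage_set_test()].
#' @param alpha significance level (default 0.05).
#' @return data.frame of per-set results with a `significant` column,
#'   sorted by p; attribute `universe` holds the tested gene universe.
#' @export
enrich_pathways <- function(relations, dems, degs, sets, gene_stats,
                            strategy = c("A", "B"),
                            direction = "two_way", alpha = 0.05) {
  strategy <- match.arg(strategy)
  dem_ids <- as.character(dems$feature_id)
  deg_ids <- if (is.data.frame(degs)) as.character(degs$feature_id) else as.character(degs)
  targets <- unique(relations$gene_id[relations$mirna_id %in% dem_ids])
  if (strategy == "B") targets <- intersect(targets, deg_ids)
  universe <- gene_stats[intersect(targets, names(gene_stats))]
  if (length(universe) < 2) {
    empty <- data.frame(set_name = character(), direction = character(),
                        set_size_tested = integer(), n_absent = integer(),
                        z = numeric(), p = numeric(), testable = logical(),
                        strategy = character(), significant = logical(),
                        stringsAsFactors = FALSE)
    return(structure(empty, universe = character(0)))
  }
  out <- do.call(rbind, lapply(names(sets), function(nm) {
    gage_set_test(universe, sets[[nm]], direction = direction, set_name = nm)
  }))
  if (is.null(out)) {
    out <- gage_set_test(universe, character(0), direction = direction)[0, ]
  }
  out$strategy <- if (nrow(out)) strategy else character(0)
  out$significant <- out$testable & !is.na(out$p) & out$p < alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, universe = names(universe))
}
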