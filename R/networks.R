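#' Induce the DEM-centered post-transcriptional network
#'
#' Nodes are the selected differential miRNAs plus their supported target
#' genes; edges are the supported relations. Gene nodes present in the DEG
#' table (same contrast) are flagged; miRNA nodes carry their modulation
#' direction so up- and down-regulated components can be reported
#' separately.
#'
#' @param relations [support_targets()] output.
#' @param dems data.frame of selected differential miRNAs (needs
#'   `feature_id`; `direction` or `log2fc` used for the direction flag),
#'   e.g. from [select_dems()].
#' @param degs optional data.frame (or character vector) of differential
#'   genes for the same contrast.
#' @return A [regulatory_network()] whose node set is exactly the DEMs and
#'   their supported targets.
#' @export
induce_dem_network <- function(relations, dems, degs = NULL) {
  dem_ids <- as.character(dems$feature_id)
  if (!length(dem_ids)) return(regulatory_network())
  deg_ids <- if (is.null(degs)) character(0) else
    if (is.data.frame(degs)) as.character(degs$feature_id) else as.character(degs)
  dir <- if (!is.null(dems$direction)) as.character(dems$direction)
  else if (!is.null(dems$log2fc)) ifelse(dems$log2fc > 0, "up", "down")
  else rep(NA_character_, length(dem_ids))
  rel <- relations[relations$mirna_id %in% dem_ids, , drop = FALSE]
  gene_ids <- unique(rel$gene_id)
  nodes <- rbind(
    data.frame(id = dem_ids, type = "miRNA", direction = dir,
               is_dem = TRUE, is_deg = FALSE, stringsAsFactors = FALSE),
    if (length(gene_ids)) data.frame(id = gene_ids, type = "gene",
                                     direction = NA_character_, is_dem = FALSE,
                                     is_deg = gene_ids %in% deg_ids,
                                     stringsAsFactors = FALSE))
  edges <- if (nrow(rel)) data.frame(from = rel$mirna_id, to = rel$gene_id,
                                     type = "mirna_target", r = rel$r, p = rel$p,
                                     q = rel$q, stringsAsFactors = FALSE)
  else data.frame()
  if (is.null(nodes) || !nrow(nodes)) return(regulatory_network())
  regulatory_network(nodes, edges)
}

#' Connected components of a regulatory network
#'
#' Undirected connectivity; components are returned largest first.
#'
#' @param network a `regulatory_network`.
#' @return List of character vectors of node IDs.
#' @export
network_components <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  if (!nrow(network$nodes)) return(list())
  comp <- igraph::components(igraph::as_undirected(as_igraph(network)))
  out <- split(names(comp$membership), comp$membership)
  out <- out[order(-vapply(out, length, 1L))]
  unname(lapply(out, as.character))
}

#' Build the mixed miRNA-TF regulatory network
#'
#' Combines the supported post-transcriptional relations with candidate
#' transcriptional edges from a validated TF-interaction table. Genes are
#' first restricted to the `top_gene_fraction` with the greatest expression
#' differences (maximum absolute log2 fold change over the T-vs-N and
#' M-vs-T contrasts). Candidate TF edges are scored by Pearson correlation
#' of the two members' profiles over matched samples and kept at
#' `q <= q_max` after BH correction within each edge class; TF edges accept
#' either correlation sign (activation or repression), while miRNA-target
#' edges require negative correlation. Edges are ranked by `|r|`.
#'
#' @param mirna_matrix,gene_matrix expression matrices (TF expression rows
#'   live in the gene matrix).
#' @param sheet [sample_sheet()].
#' @param relations supported miRNA-target relations ([support_targets()]).
#' @param tf_interactions interaction data.frame ([read_interactions()]).
#' @param dems optional DEM table restricting the miRNA universe.
#' @param top_gene_fraction fraction of most-differential genes kept
#'   (default 0.75).
#' @param q_max FDR threshold for TF edges and re-screening of miRNA edges
#'   (default 0.05).
#' @return A `regulatory_network`; attribute `n_dropped_tf_edges` counts
#'   candidate edges whose TF had no expression profile.
#' @export
build_mixed_network <- function(mirna_matrix, gene_matrix, sheet, relations,
                                tf_interactions, dems = NULL,
                                top_gene_fraction = 0.75, q_max = 0.05) {
  if (top_gene_fraction <= 0 || top_gene_fraction > 1) {
    stop("top_gene_fraction must lie in (0, 1]")
  }
  matched <- match_samples(mirna_matrix, gene_matrix, sheet)
  tf_ids <- unique(tf_interactions$regulator_id)
  mirna_universe <- if (is.null(dems)) unique(relations$mirna_id)
  else intersect(unique(relations$mirna_id), as.character(dems$feature_id))

  # rank genes by the largest absolute class-mean difference
  tiss <- tissue_of(sheet, matched)
  G <- unclass(gene_matrix)[, matched, drop = FALSE]
  cm <- function(cl) rowMeans(G[, tiss == cl, drop = FALSE])
  mN <- cm("N"); mT <- cm("T"); mM <- cm("M")
  score <- pmax(abs(mT - mN), abs(mM - mT))
  keep_n <- max(1L, floor(top_gene_fraction * nrow(G)))
  kept_genes <- rownames(G)[sort(utils::head(order(score, decreasing = TRUE), keep_n))]

  # post-transcriptional edges restricted to the kept universe
  rel <- relations[relations$mirna_id %in% mirna_universe &
                     relations$gene_id %in% kept_genes &
                     relations$r < 0 & relations$q <= q_max, , drop = FALSE]

  # candidate TF edges scored by expression correlation
  tfx <- tf_interactions
  has_profile <- tfx$regulator_id %in% rownames(gene_matrix)
  n_dropped <- sum(!has_profile)
  tfx <- tfx[has_profile, , drop = FALSE]
  tfx <- tfx[(tfx$target_kind == "gene" & tfx$target_id %in% kept_genes) |
               (tfx$target_kind == "miRNA" & tfx$target_id %in% mirna_universe), ,
             drop = FALSE]
  score_edges <- function(sub, target_matrix) {
    if (!nrow(sub)) {
      return(data.frame(from = character(), to = character(), r = numeric(),
                        p = numeric(), stringsAsFactors = FALSE))
    }
    rp <- vapply(seq_len(nrow(sub)), function(i) {
      x <- unclass(gene_matrix)[sub$regulator_id[i], matched]
      y <- unclass(target_matrix)[sub$target_id[i], matched]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(c(NA_real_, NA_real_))
      cc <- correlate(x, y)
      c(cc$r, cc$p)
    }, numeric(2))
    data.frame(from = sub$regulator_id, to = sub$target_id,
               r = rp[1, ], p = rp[2, ], stringsAsFactors = FALSE)
  }
  eg <- score_edges(tfx[tfx$target_kind == "gene", , drop = FALSE], gene_matrix)
  em <- score_edges(tfx[tfx$target_kind == "miRNA", , drop = FALSE], mirna_matrix)
  eg <- eg[!is.na(eg$r), , drop = FALSE]
  em <- em[!is.na(em$r), , drop = FALSE]
  eg$q <- bh_adjust(eg$p); em$q <- bh_adjust(em$p)
  eg <- eg[eg$q <= q_max, , drop = FALSE]
  em <- em[em$q <= q_max, , drop = FALSE]

  edges <- rbind(
    if (nrow(rel)) data.frame(from = rel$mirna_id, to = rel$gene_id,
                              type = "mirna_target", r = rel$r, p = rel$p,
                              q = rel$q, stringsAsFactors = FALSE),
    if (nrow(eg)) cbind(eg[, c("from", "to")], type = "tf_gene",
                        eg[, c("r", "p", "q")]),
    if (nrow(em)) cbind(em[, c("from", "to")], type = "tf_mirna",
                        em[, c("r", "p", "q")]))
  if (is.null(edges)) edges <- data.frame()
  if (nrow(edges)) edges <- edges[order(-abs(edges$r)), , drop = FALSE]

  node_ids <- unique(c(edges$from, edges$to))
  node_type <- ifelse(node_ids %in% tf_ids, "TF",
                      ifelse(node_ids %in% rownames(mirna_matrix), "miRNA", "gene"))
  dem_ids <- if (is.null(dems)) character(0) else as.character(dems$feature_id)
  nodes <- data.frame(id = node_ids, type = node_type,
                      direction = NA_character_,
                      is_dem = node_ids %in% dem_ids, is_deg = FALSE,
                      stringsAsFactors = FALSE)
  net <- if (length(node_ids)) regulatory_network(nodes, edges) else regulatory_network()
  attr(net, "n_dropped_tf_edges") <- n_dropped
  attr(net, "kept_genes") <- kept_genes
  net
}

#' Enumerate triangular mixed miRNA-TF circuits
#'
#' Finds the two feed-forward circuit types among retained edges:
#' `TF_driven` (one TF regulates both a miRNA and that miRNA's supported
#' target gene: edges TF->miRNA, TF->gene, miRNA-|gene) and `miRNA_driven`
#' (one miRNA represses both a TF and a gene that TF regulates: edges
#' miRNA-|TF, miRNA-|gene, TF->gene). Each circuit's `combined_p` is
#' Fisher's combination of its three edge p-values; circuits are
#' deduplicated on (type, TF, miRNA, gene) and sorted by `combined_p`.
#'
#' @param network a `regulatory_network`, typically from
#'   [build_mixed_network()].
#' @return data.frame: circuit_type, tf, mirna, gene, r_tf_mirna /
#'   r_mirna_tf, r_tf_gene, r_mirna_gene, combined_p.
#' @export
enumerate_circuits <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  ed <- network$edges
  ntype <- stats::setNames(network$nodes$type, network$nodes$id)
  empty <- data.frame(circuit_type = character(), tf = character(),
                      mirna = character(), gene = character(),
                      r_tf_edge = numeric(), r_tf_gene = numeric(),
                      r_mirna_gene = numeric(), combined_p = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(ed) || !any(ntype == "TF")) return(empty)
  key <- function(a, b) paste(a, b, sep = "\r")
  tf_gene <- ed[ed$type == "tf_gene", , drop = FALSE]
  tf_mirna <- ed[ed$type == "tf_mirna", , drop = FALSE]
  mt <- ed[ed$type == "mirna_target", , drop = FALSE]
  mt_gene <- mt[ntype[mt$to] == "gene", , drop = FALSE]   # miRNA -| gene
  mt_tf <- mt[ntype[mt$to] == "TF", , drop = FALSE]       # miRNA -| TF
  rows <- list()
  add <- function(type, tf, m, g, e_tf, e_tfg, e_mg) {
    rows[[length(rows) + 1]] <<- data.frame(
      circuit_type = type, tf = tf, mirna = m, gene = g,
      r_tf_edge = e_tf$r, r_tf_gene = e_tfg$r, r_mirna_gene = e_mg$r,
      combined_p = fisher_combine(c(e_tf$p, e_tfg$p, e_mg$p)),
      stringsAsFactors = FALSE)
  }
  tg_idx <- split(seq_len(nrow(tf_gene)), tf_gene$from)
  mg_idx <- split(seq_len(nrow(mt_gene)), mt_gene$from)
  # TF-driven: TF t -> miRNA m, t -> gene g, m -| g
  for (i in seq_len(nrow(tf_mirna))) {
    t <- tf_mirna$from[i]; m <- tf_mirna$to[i]
    gi <- tg_idx[[t]]; mi <- mg_idx[[m]]
    if (is.null(gi) || is.null(mi)) next
    shared <- intersect(tf_gene$to[gi], mt_gene$to[mi])
    for (g in shared) {
      add("TF_driven", t, m, g,
          tf_mirna[i, ],
          tf_gene[gi[match(g, tf_gene$to[gi])], ],
          mt_gene[mi[match(g, mt_gene$to[mi])], ])
    }
  }
  # miRNA-driven: miRNA m -| TF t, m -| gene g, t -> g
  for (i in seq_len(nrow(mt_tf))) {
    m <- mt_tf$from[i]; t <- mt_tf$to[i]
    gi <- tg_idx[[t]]; mi <- mg_idx[[m]]
    if (is.null(gi) || is.null(mi)) next
    shared <- intersect(tf_gene$to[gi], mt_gene$to[mi])
    for (g in shared) {
      add("miRNA_driven", t, m, g,
          mt_tf[i, ],
          tf_gene[gi[match(g, tf_gene$to[gi])], ],
          mt_gene[mi[match(g, mt_gene$to[mi])], ])
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(paste(out$circuit_type, out$tf, out$mirna, out$gene)), ,
             drop = FALSE]
  out <- out[order(out$combined_p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Fisher's method: -2 sum(log p) ~ chi^2 with 2k df under the joint null
fisher_combine <- function(p) {
  p <- pmax(p, .Machine$double.xmin)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}
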