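# Small fixtures and independent oracles used across the suite.

tiny_matrix <- function(values = NULL, kind = "miRNA", n_feat = 3, n_samp = 4,
                        seed = 1) {
  if (is.null(values)) {
    set.seed(seed)
    values <- matrix(rnorm(n_feat * n_samp, mean = 6), nrow = n_feat)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  expression_matrix(values, kind)
}

tiny_sheet <- function(tissues) {
  n <- length(tissues)
  sample_sheet(sprintf("s%02d", seq_len(n)),
               sprintf("p%02d", seq_len(n)), tissues)
}

# a no-effect cohort configuration: iid features, exchangeable samples
null_cohort_config <- function(seed, n_mirnas = 200, n_genes = 50,
                               patient_effect_sd = 0) {
  cohort_config(seed = seed, n_mirnas = n_mirnas, n_genes = n_genes,
                n_planted_dems = c(TvN = 0, MvT = 0), n_planted_degs = 0,
                n_planted_repressions = 0, n_decoy_predictions = 0,
                n_planted_circuits = c(TF_driven = 0, miRNA_driven = 0),
                n_decoy_tfs = 0, n_decoy_tf_edges = 0,
                patient_effect_sd = patient_effect_sd)
}

# hand-written BH step-up, independent of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# union-find connected components over an undirected edge list
components_oracle <- function(node_ids, from, to) {
  parent <- stats::setNames(node_ids, node_ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(from)) parent[[find(from[i])]] <- find(to[i])
  roots <- vapply(node_ids, find, "")
  unname(lapply(split(node_ids, roots), sort))
}

# all-triples scan for the two mixed circuit types
circuits_oracle <- function(network) {
  nodes <- network$nodes; ed <- network$edges
  has <- function(a, b, type) {
    any(ed$from == a & ed$to == b & ed$type == type)
  }
  tfs <- nodes$id[nodes$type == "TF"]
  mirnas <- nodes$id[nodes$type == "miRNA"]
  genes <- nodes$id[nodes$type == "gene"]
  out <- list()
  for (t in tfs) for (m in mirnas) for (g in genes) {
    if (has(t, m, "tf_mirna") && has(t, g, "tf_gene") && has(m, g, "mirna_target")) {
      out[[length(out) + 1]] <- c("TF_driven", t, m, g)
    }
    if (has(m, t, "mirna_target") && has(m, g, "mirna_target") && has(t, g, "tf_gene")) {
      out[[length(out) + 1]] <- c("miRNA_driven", t, m, g)
    }
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, paste, "", collapse = "|"))
}

# random typed mixed network for oracle comparisons
random_mixed_network <- function(seed, n_tf = 5, n_mirna = 8, n_gene = 12,
                                 p_edge = 0.2) {
  set.seed(seed)
  nodes <- data.frame(
    id = c(sprintf("t%d", 1:n_tf), sprintf("m%d", 1:n_mirna),
           sprintf("g%d", 1:n_gene)),
    type = c(rep("TF", n_tf), rep("miRNA", n_mirna), rep("gene", n_gene)),
    stringsAsFactors = FALSE)
  edges <- list()
  add_edges <- function(froms, tos, type) {
    for (a in froms) for (b in tos) {
      if (runif(1) < p_edge) {
        edges[[length(edges) + 1]] <<- data.frame(
          from = a, to = b, type = type, r = runif(1, -1, 1),
          p = runif(1, 1e-6, 0.05), q = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  tfs <- nodes$id[nodes$type == "TF"]
  ms <- nodes$id[nodes$type == "miRNA"]
  gs <- nodes$id[nodes$type == "gene"]
  add_edges(tfs, ms, "tf_mirna")
  add_edges(tfs, gs, "tf_gene")
  add_edges(ms, gs, "mirna_target")
  add_edges(ms, tfs, "mirna_target")  # miRNAs repressing TFs
  regulatory_network(nodes, if (length(edges)) do.call(rbind, edges) else data.frame())
}

# Breslow partial log-likelihood for a univariate Cox model (no ties beyond
# Breslow handling); independent grid/optimize oracle for coxph
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

cox_oracle_beta <- function(time, event, x, lower = -8, upper = 8) {
  stats::optimize(function(b) breslow_loglik(b, time, event, x),
                  c(lower, upper), maximum = TRUE, tol = 1e-9)$maximum
}
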