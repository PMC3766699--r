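#' Construct a typed regulatory network
#'
#' Container for the post-transcriptional and mixed miRNA-TF networks. Nodes
#' are typed (`miRNA`, `gene`, `TF`) and carry differential-expression
#' annotation; edges are typed (`mirna_target` for miRNA repression of a
#' target, `tf_gene`, `tf_mirna` for transcriptional regulation) and carry the
#' supporting correlation evidence.
#'
#' @param nodes data.frame with columns `id`, `type` and optionally
#'   `direction` ("up"/"down"/NA), `is_dem`, `is_deg`.
#' @param edges data.frame with columns `from`, `to`, `type` and optionally
#'   `r`, `p`, `q`.
#' @return An object of class `regulatory_network`.
#' @export
regulatory_network <- function(nodes = data.frame(), edges = data.frame()) {
  if (!nrow(nodes)) {
    nodes <- data.frame(id = character(), type = character(),
                        direction = character(), is_dem = logical(),
                        is_deg = logical(), stringsAsFactors = FALSE)
  }
  if (!nrow(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        type = character(), r = numeric(), p = numeric(),
                        q = numeric(), stringsAsFactors = FALSE)
  }
  for (col in c("direction")) if (is.null(nodes[[col]])) nodes[[col]] <- NA_character_
  for (col in c("is_dem", "is_deg")) if (is.null(nodes[[col]])) nodes[[col]] <- FALSE
  for (col in c("r", "p", "q")) if (is.null(edges[[col]])) edges[[col]] <- NA_real_
  nodes <- nodes[, c("id", "type", "direction", "is_dem", "is_deg")]
  edges <- edges[, c("from", "to", "type", "r", "p", "q")]
  if (anyDuplicated(nodes$id)) stop("duplicate node IDs")
  if (any(is.na(nodes$type)) || !all(nodes$type %in% c("miRNA", "gene", "TF"))) {
    stop("every node must be typed miRNA, gene or TF")
  }
  if (!all(edges$type %in% c("mirna_target", "tf_gene", "tf_mirna"))) {
    stop("unknown edge type")
  }
  missing_ep <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing_ep)) {
    stop("edge endpoint(s) not in node table: ", paste(missing_ep, collapse = ", "))
  }
  # miRNA-target edges are bipartite: miRNA source, gene/TF target
  if (nrow(edges)) {
    ntype <- stats::setNames(nodes$type, nodes$id)
    mt <- edges$type == "mirna_target"
    if (any(mt & ntype[edges$from] != "miRNA")) {
      stop("mirna_target edge with non-miRNA source")
    }
    if (any(mt & !(ntype[edges$to] %in% c("gene", "TF")))) {
      stop("mirna_target edge with non-gene target")
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d nodes (%s), %d edges (%s)\n",
              nrow(x$nodes),
              paste(sprintf("%s: %d", names(table(x$nodes$type)),
                            as.integer(table(x$nodes$type))), collapse = ", "),
              nrow(x$edges),
              paste(sprintf("%s: %d", names(table(x$edges$type)),
                            as.integer(table(x$edges$type))), collapse = ", ")))
  invisible(x)
}

#' Convert a regulatory network to an igraph object
#'
#' @param network a `regulatory_network`.
#' @return An `igraph` graph with node/edge attributes preserved.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  igraph::graph_from_data_frame(network$edges,
                                directed = TRUE,
                                vertices = network$nodes)
}

#' Serialize a network to edge-list TSV and GraphML
#'
#' Writes `<prefix>.nodes.tsv`, `<prefix>.edges.tsv` and `<prefix>.graphml`.
#' Empty networks produce header-only tables. Untyped nodes are rejected by
#' the `regulatory_network` constructor upstream.
#'
#' @param network a `regulatory_network`.
#' @param prefix output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_network <- function(network, prefix) {
  stopifnot(inherits(network, "regulatory_network"))
  paths <- paste0(prefix, c(".nodes.tsv", ".edges.tsv", ".graphml"))
  utils::write.table(network$nodes, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(network$edges, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(network$nodes)) {
    igraph::write_graph(as_igraph(network), paths[3], format = "graphml")
  } else {
    igraph::write_graph(igraph::make_empty_graph(), paths[3], format = "graphml")
  }
  invisible(paths)
}

#' Read a network back from its node/edge TSV pair
#'
#' @param prefix the prefix passed to [write_network()].
#' @return A `regulatory_network`.
#' @export
read_network <- function(prefix) {
  nodes <- utils::read.delim(paste0(prefix, ".nodes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  edges <- utils::read.delim(paste0(prefix, ".edges.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  if (nrow(nodes)) nodes$id <- as.character(nodes$id)
  regulatory_network(nodes, edges)
}
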