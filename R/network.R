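#' Construct a miRNA-miRNA network object
#'
#' The central result container: an undirected, self-loop-free graph over
#' miRNAs. Edges are stored once in canonical order (`mir_a < mir_b`) in a
#' tibble that may carry arbitrary score columns; the full tested pair and
#' triplet tables can travel along for export.
#'
#' @param edges Tibble whose first two columns are miRNA ids; further columns
#'   become edge attributes.
#' @param nodes Character vector of node ids. Defaults to the edge endpoints.
#' @param relation Edge relation tag used in SIF export (for example `"mre"`
#'   for modulation edges).
#' @param pairs,triplets Optional full result tables retained for export.
#' @param params Optional list of inference parameters (recorded metadata).
#' @return An object of class `mirna_network`.
#' @export
mirna_network <- function(edges, nodes = NULL, relation = "mre",
                          pairs = NULL, triplets = NULL, params = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  edges <- tibble::as_tibble(edges)
  names(edges)[1:2] <- c("mir_a", "mir_b")
  if (nrow(edges) > 0L) {
    a <- pmin(edges$mir_a, edges$mir_b)
    b <- pmax(edges$mir_a, edges$mir_b)
    if (any(a == b)) stop("self-loops are not allowed")
    edges$mir_a <- a
    edges$mir_b <- b
    edges <- dplyr::distinct(edges, .data$mir_a, .data$mir_b, .keep_all = TRUE)
    edges <- dplyr::arrange(edges, .data$mir_a, .data$mir_b)
  }
  if (is.null(nodes)) nodes <- union(edges$mir_a, edges$mir_b)
  structure(list(nodes = sort(unique(as.character(nodes))), edges = edges,
                 relation = relation, pairs = pairs, triplets = triplets,
                 params = params),
            class = "mirna_network")
}

#' Per-node degree of a miRNA network
#' @param net A `mirna_network`.
#' @return Named integer vector over all network nodes (isolated nodes get 0).
#' @export
network_degree <- function(net) {
  stopifnot(inherits(net, "mirna_network"))
  deg <- setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges) > 0L) {
    tab <- table(c(net$edges$mir_a, net$edges$mir_b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' @export
print.mirna_network <- function(x, ...) {
  cat(sprintf("miRNA network ('%s'): %d nodes, %d edges\n",
              x$relation, length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0L) {
    deg <- network_degree(x)
    cat(sprintf("degree: mean %.1f, range %d-%d\n", mean(deg), min(deg), max(deg)))
  }
  invisible(x)
}

#' Convert a miRNA network to an igraph graph
#' @param net A `mirna_network`.
#' @return An undirected `igraph` graph with edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "mirna_network"))
  igraph::graph_from_data_frame(as.data.frame(net$edges), directed = FALSE,
                                vertices = net$nodes)
}

#' Export a network in Cytoscape SIF format
#'
#' Each line is `mirA <TAB> relation <TAB> mirB`; isolated nodes are written
#' as bare node lines, as SIF allows.
#'
#' @param net A `mirna_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "mirna_network"))
  iso <- setdiff(net$nodes, union(net$edges$mir_a, net$edges$mir_b))
  lines <- character(0)
  if (nrow(net$edges) > 0L) {
    lines <- paste(net$edges$mir_a, net$relation, net$edges$mir_b, sep = "\t")
  }
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Export a network in GraphML format (with edge score attributes)
#' @inheritParams write_sif
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Read a network from a GraphML file
#' @param path Path to a GraphML file written by [write_graphml()].
#' @param relation Relation tag to attach.
#' @return A `mirna_network`.
#' @export
read_graphml <- function(path, relation = "mre") {
  g <- igraph::read_graph(path, format = "graphml")
  edges <- igraph::as_data_frame(g, what = "edges")
  names(edges)[1:2] <- c("mir_a", "mir_b")
  mirna_network(tibble::as_tibble(edges), nodes = igraph::V(g)$name,
                relation = relation)
}

#' @export
tidy.mirna_network <- function(x, ...) x$edges

#' @export
glance.mirna_network <- function(x, ...) {
  deg <- if (length(x$nodes) > 0L) network_degree(x) else integer(0)
  tibble::tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
                 mean_degree = if (length(deg)) mean(deg) else NA_real_,
                 max_degree = if (length(deg)) max(deg) else NA_integer_)
}
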