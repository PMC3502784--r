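#' Hub and connectivity report for a miRNA network
#'
#' Degree-based hub analysis: per-node degree, rank, and the fraction of the
#' network's other nodes each miRNA connects to, plus the top-`k` hub list
#' (ties broken lexicographically but reported as tied via the rank column).
#'
#' @param net A nonempty `mirna_network`.
#' @param k Size of the hub list (default 11).
#' @return A list of class `hub_report`: `nodes` (tibble with `mirna`,
#'   `degree`, `rank`, `fraction`, `is_hub`), `hubs` (character), and
#'   `summary` (mean/min/max degree).
#' @export
hub_report <- function(net, k = 11) {
  stopifnot(inherits(net, "mirna_network"))
  if (length(net$nodes) == 0L) stop("empty network")
  deg <- network_degree(net)
  tab <- tibble::tibble(mirna = names(deg), degree = as.integer(deg))
  tab <- dplyr::arrange(tab, dplyr::desc(.data$degree), .data$mirna)
  tab$rank <- as.integer(rank(-tab$degree, ties.method = "min"))
  denom <- max(length(net$nodes) - 1L, 1L)
  tab$fraction <- tab$degree / denom
  k <- min(k, nrow(tab))
  tab$is_hub <- seq_len(nrow(tab)) <= k
  structure(list(nodes = tab, hubs = tab$mirna[tab$is_hub],
                 summary = list(mean_degree = mean(tab$degree),
                                min_degree = min(tab$degree),
                                max_degree = max(tab$degree))),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("hub report: degree mean %.1f, range %d-%d\n",
              x$summary$mean_degree, x$summary$min_degree, x$summary$max_degree))
  cat("top hubs:", paste(utils::head(x$hubs, 11), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.hub_report <- function(x, ...) x$nodes

#' @export
glance.hub_report <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), mean_degree = x$summary$mean_degree,
                 min_degree = x$summary$min_degree,
                 max_degree = x$summary$max_degree)
}

#' Shared-target comparator network
#'
#' The first bias control: connects two miRNAs when their shared mRNA-target
#' count is larger than expected by chance under a hypergeometric draw from
#' the urn of all target mRNAs in the network. This network sees only the
#' interaction table — by construction it is expression-free — so any
#' agreement with the modulation network would indicate that hubs merely
#' reflect shared binding sites.
#'
#' @param targets A `target_network`.
#' @param alpha Significance threshold on the hypergeometric upper-tail p.
#' @return A `mirna_network` with edge attributes `shared` and `p_value`;
#'   the full pair table is kept in `$pairs`.
#' @export
shared_target_network <- function(targets, alpha = 0.05) {
  stopifnot(inherits(targets, "target_network"), nrow(targets) > 0L)
  mirnas <- sort(unique(targets$mirna))
  urn <- sort(unique(targets$mrna))
  inc <- matrix(FALSE, length(mirnas), length(urn),
                dimnames = list(mirnas, urn))
  inc[cbind(match(targets$mirna, mirnas), match(targets$mrna, urn))] <- TRUE
  shared <- tcrossprod(inc * 1)
  sizes <- rowSums(inc)
  U <- length(urn)
  idx <- which(upper.tri(shared), arr.ind = TRUE)
  n_shared <- as.integer(shared[idx])
  pairs <- tibble::tibble(
    mir_a = mirnas[idx[, 1L]], mir_b = mirnas[idx[, 2L]],
    shared = n_shared,
    p_value = phyper(n_shared - 1, sizes[idx[, 1L]],
                     U - sizes[idx[, 1L]], sizes[idx[, 2L]],
                     lower.tail = FALSE))
  edges <- pairs[pairs$p_value < alpha & pairs$shared > 0L, , drop = FALSE]
  mirna_network(edges, nodes = mirnas, relation = "shared_target",
                pairs = pairs, params = list(alpha = alpha, urn_size = U))
}

#' Expression-correlation comparator network
#'
#' The second bias control: connects miRNA pairs whose expression is
#' significantly correlated (two-sided test on the absolute correlation,
#' Benjamini-Hochberg adjusted). Spearman rank correlation is the default,
#' consistent with the rank-based MI estimator; p-values use the
#' t-approximation for the correlation coefficient.
#'
#' @param mir miRNA expression matrix with at least 10 samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha Threshold on the adjusted p-value.
#' @param adjust Multiple-testing adjustment (default `"BH"`).
#' @return A `mirna_network` with edge attributes `correlation`, `p_value`,
#'   `q_value`; the full pair table is kept in `$pairs`.
#' @export
correlation_network <- function(mir, method = c("spearman", "pearson"),
                                alpha = 0.05, adjust = "BH") {
  method <- match.arg(method)
  mir <- validate_expression(mir)
  n <- ncol(mir)
  if (n < 10L) stop("need at least 10 samples")
  constant <- apply(mir, 1L, function(x) diff(range(x)) == 0)
  if (any(constant)) {
    warning(sprintf("dropping %d constant rows", sum(constant)))
    mir <- mir[!constant, , drop = FALSE]
  }
  rho <- cor(t(mir), method = method)
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  pairs <- tibble::tibble(mir_a = rownames(mir)[idx[, 1L]],
                          mir_b = rownames(mir)[idx[, 2L]],
                          correlation = r, p_value = p,
                          q_value = p.adjust(p, adjust))
  edges <- pairs[pairs$q_value < alpha, , drop = FALSE]
  mirna_network(edges, nodes = rownames(mir), relation = "correlation",
                pairs = pairs,
                params = list(alpha = alpha, method = method, adjust = adjust))
}

#' Compare two miRNA networks
#'
#' Overlap diagnostics used to show (or refute) that two network
#' constructions tell the same story: Jaccard similarity of edge sets,
#' Spearman correlation of node degrees over the union of nodes, and the
#' hubs of `a` that are not hubs of `b`.
#'
#' @param a,b `mirna_network` objects.
#' @param k Hub-list size used for the hub comparison (default 11).
#' @return A list of class `network_comparison` with `jaccard`,
#'   `degree_rank_correlation`, `hubs_a_not_b`, and edge counts.
#' @export
compare_networks <- function(a, b, k = 11) {
  stopifnot(inherits(a, "mirna_network"), inherits(b, "mirna_network"))
  key <- function(net) paste(net$edges$mir_a, net$edges$mir_b, sep = "\r")
  ka <- key(a)
  kb <- key(b)
  uni <- union(ka, kb)
  jaccard <- if (length(uni) == 0L) NA_real_ else
    length(intersect(ka, kb)) / length(uni)
  nodes <- union(a$nodes, b$nodes)
  da <- db <- setNames(numeric(length(nodes)), nodes)
  da[names(network_degree(a))] <- network_degree(a)
  db[names(network_degree(b))] <- network_degree(b)
  drc <- if (length(nodes) >= 2L && sd(da) > 0 && sd(db) > 0) {
    cor(da, db, method = "spearman")
  } else NA_real_
  hubs_a <- if (length(a$nodes)) hub_report(a, k)$hubs else character(0)
  hubs_b <- if (length(b$nodes)) hub_report(b, k)$hubs else character(0)
  structure(list(jaccard = jaccard, degree_rank_correlation = drc,
                 hubs_a_not_b = setdiff(hubs_a, hubs_b),
                 n_edges_a = nrow(a$edges), n_edges_b = nrow(b$edges),
                 n_shared_edges = length(intersect(ka, kb))),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("edge Jaccard %.3f (%d vs %d edges, %d shared); degree rank cor %.3f\n",
              x$jaccard, x$n_edges_a, x$n_edges_b, x$n_shared_edges,
              x$degree_rank_correlation))
  invisible(x)
}

#' @export
glance.network_comparison <- function(x, ...) {
  tibble::tibble(jaccard = x$jaccard,
                 degree_rank_correlation = x$degree_rank_correlation,
                 n_edges_a = x$n_edges_a, n_edges_b = x$n_edges_b,
                 n_shared_edges = x$n_shared_edges)
}
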