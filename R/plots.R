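#' Plot a miRNA network
#'
#' Force-directed layout (Fruchterman-Reingold, seed-fixed) with node size
#' proportional to degree — the conventional view of a modulation network
#' where hubs stand out by size.
#'
#' @param net A `mirna_network` with at least one edge.
#' @param label_top Label the `label_top` highest-degree nodes (default 5).
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_network <- function(net, label_top = 5, seed = 0) {
  stopifnot(inherits(net, "mirna_network"))
  if (nrow(net$edges) == 0L) stop("nothing to plot: network has no edges")
  g <- as_igraph(net)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(mirna = igraph::V(g)$name, x = xy[, 1L],
                          y = xy[, 2L],
                          degree = as.numeric(igraph::degree(g)))
  seg <- dplyr::left_join(net$edges[, c("mir_a", "mir_b")],
                          dplyr::rename(nodes, x0 = "x", y0 = "y"),
                          by = c(mir_a = "mirna"))
  seg <- dplyr::left_join(seg, dplyr::rename(nodes[, c("mirna", "x", "y")],
                                             x1 = "x", y1 = "y"),
                          by = c(mir_b = "mirna"))
  lab <- dplyr::slice_max(nodes, .data$degree, n = label_top,
                          with_ties = FALSE)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y, size = .data$degree),
                        colour = "steelblue") +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(.data$x, .data$y, label = .data$mirna),
                       vjust = -1, size = 3) +
    ggplot2::scale_size_continuous(range = c(1, 6)) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "degree")
}

#' @describeIn pca_view Scatter plot of the first two components, optionally
#'   coloured by a per-sample grouping.
#' @param object A `pca_view`.
#' @param colour Optional vector (named by sample id or in score order) used
#'   to colour points.
#' @param ... Ignored.
#' @export
autoplot.pca_view <- function(object, colour = NULL, ...) {
  df <- object$scores
  if (!is.null(colour)) {
    df$colour <- if (!is.null(names(colour))) colour[df$sample_id] else colour
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1L]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2L])) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
}

#' @describeIn random_signature_null Histogram of null accuracies with the
#'   signature's accuracy marked.
#' @param object A `classifier_null`.
#' @param ... Ignored.
#' @export
autoplot.classifier_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$signature_accuracy,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "random-signature CV accuracy", y = "count",
                  title = sprintf("signature accuracy %.3f, empirical p = %.3g",
                                  object$signature_accuracy,
                                  object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' @describeIn survival_analysis Kaplan-Meier step curves for the two risk
#'   groups.
#' @param object A `signature_survival`.
#' @param ... Ignored.
#' @export
autoplot.signature_survival <- function(object, ...) {
  km <- object$km
  strata <- rep(names(km$strata), km$strata)
  df <- tibble::tibble(time = km$time, surv = km$surv,
                       group = sub("^gf=", "", strata))
  base <- tibble::tibble(time = 0, surv = 1,
                         group = unique(df$group))
  df <- dplyr::bind_rows(base, df)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "recurrence-free fraction",
                  colour = "signature\nexpression",
                  title = sprintf("HR %.2f (95%% CI %.2f-%.2f), log-rank p = %.3g",
                                  object$hazard_ratio, object$hr_ci[1L],
                                  object$hr_ci[2L], object$logrank_p)) +
    ggplot2::theme_minimal()
}
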