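#' Run the full synthetic-to-evaluation pipeline
#'
#' One call that exercises every stage end to end on a synthetic cohort:
#' simulate, write the input files, infer the modulation network, build both
#' comparator networks, compare them, and evaluate the designated signature
#' (classifier null, differential expression, survival). All outputs are
#' plain-text files in `out_dir`; with a fixed seed the run is byte-for-byte
#' reproducible.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [simulation_config()].
#' @param alpha,n_perm,bins_marginal,bins_conditional,strata Passed to
#'   [infer_network()].
#' @param n_lists Random signatures for the classifier null (default 100).
#' @param seed Master seed for inference and evaluation (defaults to the
#'   config's seed).
#' @return Invisibly, a list with the in-memory results (`sim`, `network`,
#'   `shared`, `correlation`, `comparison`, `hubs`, `classifier`, `de`,
#'   `survival`).
#' @export
run_pipeline <- function(out_dir, config = simulation_config(),
                         alpha = exp(-5), n_perm = 1000, bins_marginal = 3,
                         bins_conditional = 3, strata = 2, n_lists = 100,
                         seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, ...)

  sim <- simulate_dataset(config)
  write_expression(sim$mir, path("mir.tsv"))
  write_expression(sim$mrna, path("mrna.tsv"))
  write_targets(sim$targets, path("targets.tsv"))
  write_metadata(sim$meta, path("metadata.tsv"))
  writeLines(sim$signature, path("signature.txt"))

  aligned <- align_samples(sim$mir, sim$mrna, sim$meta)
  net <- infer_network(aligned$mir, aligned$mrna, sim$targets, alpha = alpha,
                       n_perm = n_perm, bins_marginal = bins_marginal,
                       bins_conditional = bins_conditional, strata = strata,
                       seed = seed)
  write_tsv_plain(net$triplets, path("triplets.tsv"))
  write_tsv_plain(dplyr::select(net$pairs, -"mediating_targets"),
                  path("pairs.tsv"))
  write_sif(net, path("network.sif"))
  write_graphml(net, path("network.graphml"))

  shared <- shared_target_network(sim$targets)
  corr <- correlation_network(aligned$mir)
  write_sif(shared, path("shared_target.sif"))
  write_sif(corr, path("correlation.sif"))
  comparison <- compare_networks(net, shared)
  jsonlite::write_json(
    list(modulation_vs_shared = unclass(glance(comparison)),
         modulation_vs_correlation = unclass(glance(compare_networks(net, corr)))),
    path("comparison.json"), auto_unbox = TRUE, digits = 10, pretty = TRUE)

  hubs <- if (nrow(net$edges) > 0L) hub_report(net) else NULL
  if (!is.null(hubs)) write_tsv_plain(hubs$nodes, path("hubs.tsv"))

  labels <- ifelse(aligned$meta$class_label == "normal", "normal", "tumor")
  classifier <- random_signature_null(aligned$mir, labels, sim$signature,
                                      n_lists = n_lists, seed = seed)
  de <- differential_expression(aligned$mir[sim$signature, , drop = FALSE],
                                labels, log_scale = TRUE, seed = seed)
  surv <- survival_analysis(aligned$mir, sim$signature, aligned$meta,
                            seed = seed)
  write_tsv_plain(de, path("differential_expression.tsv"))
  write_tsv_plain(tidy(surv), path("survival_coefficients.tsv"))
  jsonlite::write_json(
    list(classifier = unclass(glance(classifier)),
         survival = unclass(glance(surv))),
    path("evaluation.json"), auto_unbox = TRUE, digits = 10, pretty = TRUE)

  invisible(list(sim = sim, network = net, shared = shared,
                 correlation = corr, comparison = comparison, hubs = hubs,
                 classifier = classifier, de = de, survival = surv))
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 12, trim = TRUE,
                                                scientific = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
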