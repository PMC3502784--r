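#' Permutation p-value for the modulation statistic
#'
#' Shuffles the modulator across samples `n_perm` times, recomputes
#' `delta_MI` for each shuffle and returns the pseudocount empirical p-value
#' `p = (1 + #\{delta_perm >= delta_obs\}) / (n_perm + 1)`. Only the
#' modulator is permuted, so the marginal MI term is held fixed and the null
#' distribution reflects "this mRNA carries no information about the pair's
#' coupling". The pseudocount keeps p strictly positive, which is what makes
#' the downstream Fisher combination well defined.
#'
#' Randomness comes from a dedicated, platform-independent stream seeded by
#' hashing `key` together with `seed`, so results do not depend on the order
#' in which triplets are evaluated or on R's global RNG state.
#'
#' @inheritParams delta_mi
#' @param n_perm Number of permutations (default 1000).
#' @param seed Master seed (integer).
#' @param key Optional string identifying the triplet; used to derive an
#'   order-independent per-triplet stream.
#' @param return_null If `TRUE`, also return the permuted `delta_MI` values.
#' @return A list of class `permutation_result`: `score` (a
#'   `modulation_score`), `p_value`, `n_perm`, and optionally `null_deltas`.
#' @export
permutation_p <- function(d, r, m, n_perm = 1000, seed = 0, key = "",
                          bins_marginal = 3, bins_conditional = 3, strata = 2,
                          return_null = FALSE) {
  stopifnot(n_perm >= 1)
  check_pair(d, r, bins_marginal)
  check_numeric_vector(m)
  stopifnot(length(m) == length(d))
  res <- cpp_permutation_delta(d, r, m, as.integer(bins_marginal),
                               as.integer(bins_conditional),
                               as.integer(strata), as.integer(n_perm),
                               paste(key, format(seed), sep = "\r"),
                               isTRUE(return_null))
  out <- list(
    score = structure(
      list(mi_marginal = structure(list(value = res$mi_marginal,
                                        bin_count = as.integer(bins_marginal),
                                        n = length(d)), class = "mi_estimate"),
           mi_conditional = res$mi_conditional, delta_mi = res$delta_mi,
           strata = as.integer(strata)),
      class = "modulation_score"),
    p_value = res$p_value, n_perm = as.integer(n_perm))
  if (isTRUE(return_null)) out$null_deltas <- res$null_deltas
  structure(out, class = "permutation_result")
}

#' Enumerate candidate (miRNA, miRNA, modulator) triplets
#'
#' Prior knowledge restricts the search: for every target edge `(a, m)` whose
#' miRNA and mRNA are present in the expression matrices, every other miRNA
#' `b` in the miRNA matrix forms a candidate triplet `(a, b, m)`. Each
#' unordered triple `{a, b} + m` is yielded once, in canonical order
#' (`mir_a < mir_b`). With `strict = TRUE` the modulator must be a known
#' target of *both* pair members.
#'
#' @param targets A `target_network`.
#' @param mir,mrna Expression matrices; identifiers are matched exactly
#'   against rownames, and unresolvable edges are dropped with a message.
#' @param strict Require `m` to be targeted by both miRNAs (default `FALSE`).
#' @return A tibble with columns `mir_a`, `mir_b`, `modulator`.
#' @export
enumerate_candidates <- function(targets, mir, mrna, strict = FALSE) {
  stopifnot(inherits(targets, "target_network"))
  mirs <- rownames(mir)
  keep <- targets$mirna %in% mirs & targets$mrna %in% rownames(mrna)
  if (sum(!keep) > 0L) {
    message(sprintf("dropped %d target edges unresolvable in the matrices",
                    sum(!keep)))
  }
  edges <- targets[keep, , drop = FALSE]
  if (nrow(edges) == 0L || length(mirs) < 2L) {
    stop("no resolvable candidate triplets")
  }
  cand <- tidyr::crossing(idx = seq_len(nrow(edges)), partner = mirs)
  cand <- tibble::tibble(anchor = edges$mirna[cand$idx],
                         modulator = edges$mrna[cand$idx],
                         partner = cand$partner)
  cand <- cand[cand$anchor != cand$partner, , drop = FALSE]
  out <- tibble::tibble(mir_a = pmin(cand$anchor, cand$partner),
                        mir_b = pmax(cand$anchor, cand$partner),
                        modulator = cand$modulator)
  out <- dplyr::distinct(out)
  if (strict) {
    key <- paste(targets$mirna, targets$mrna, sep = "\r")
    ok <- paste(out$mir_a, out$modulator, sep = "\r") %in% key &
      paste(out$mir_b, out$modulator, sep = "\r") %in% key
    out <- out[ok, , drop = FALSE]
    if (nrow(out) == 0L) stop("no resolvable candidate triplets in strict mode")
  }
  dplyr::arrange(out, .data$mir_a, .data$mir_b, .data$modulator)
}

#' Score candidate triplets with permutation p-values
#'
#' Computes the modulation statistic and its permutation p-value for every
#' candidate row. Each triplet gets its own RNG stream derived from
#' `(mir_a, mir_b, modulator, seed)`, so the result is independent of row
#' order.
#'
#' @param candidates Tibble from [enumerate_candidates()].
#' @inheritParams permutation_p
#' @param mir,mrna Aligned expression matrices.
#' @return The candidate tibble with columns `mi`, `cmi`, `delta_mi`,
#'   `p_value` appended.
#' @export
score_triplets <- function(candidates, mir, mrna, n_perm = 1000, seed = 0,
                           bins_marginal = 3, bins_conditional = 3,
                           strata = 2) {
  stopifnot(all(c("mir_a", "mir_b", "modulator") %in% names(candidates)))
  n <- nrow(candidates)
  mi <- cmi <- dmi <- pv <- numeric(n)
  ia <- match(candidates$mir_a, rownames(mir))
  ib <- match(candidates$mir_b, rownames(mir))
  im <- match(candidates$modulator, rownames(mrna))
  if (any(is.na(ia)) || any(is.na(ib)) || any(is.na(im))) {
    stop("candidate identifiers not resolvable in the expression matrices")
  }
  for (i in seq_len(n)) {
    key <- paste(candidates$mir_a[i], candidates$mir_b[i],
                 candidates$modulator[i], format(seed), sep = "\r")
    res <- cpp_permutation_delta(mir[ia[i], ], mir[ib[i], ], mrna[im[i], ],
                                 as.integer(bins_marginal),
                                 as.integer(bins_conditional),
                                 as.integer(strata), as.integer(n_perm),
                                 key, FALSE)
    mi[i] <- res$mi_marginal
    cmi[i] <- res$mi_conditional
    dmi[i] <- res$delta_mi
    pv[i] <- res$p_value
  }
  dplyr::mutate(tibble::as_tibble(candidates), mi = mi, cmi = cmi,
                delta_mi = dmi, p_value = pv)
}

#' Combine p-values with Fisher's method
#'
#' `X2 = -2 * sum(log(p_k))` referred to a chi-square distribution with
#' `2 N` degrees of freedom, `N` the number of p-values. With a single
#' p-value the combination is the identity.
#'
#' @param p_values Nonempty numeric vector with entries in `(0, 1]`.
#' @return A list with `x2`, `dof`, `combined_p`, `n_targets`.
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) == 0L) stop("need at least one p-value")
  if (any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  x2 <- -2 * sum(log(p_values))
  dof <- 2L * length(p_values)
  list(x2 = x2, dof = dof,
       combined_p = pchisq(x2, df = dof, lower.tail = FALSE),
       n_targets = length(p_values))
}

#' Pool triplet p-values into per-pair Fisher scores
#'
#' Triplets are grouped by unordered miRNA pair (both orientations pooled)
#' and combined with [fisher_combine()]; `n_targets` is the number of
#' mediating triplets behind the pair.
#'
#' @param triplets Scored triplet tibble from [score_triplets()].
#' @return A tibble with one row per pair: `mir_a`, `mir_b`, `x2`, `dof`,
#'   `combined_p`, `n_targets`, `mediating_targets` (list column).
#' @export
combine_pairs <- function(triplets) {
  stopifnot(all(c("mir_a", "mir_b", "p_value") %in% names(triplets)))
  dplyr::summarise(
    dplyr::group_by(triplets, .data$mir_a, .data$mir_b),
    x2 = -2 * sum(log(.data$p_value)),
    n_targets = dplyr::n(),
    dof = 2L * dplyr::n(),
    combined_p = pchisq(-2 * sum(log(.data$p_value)), df = 2L * dplyr::n(),
                        lower.tail = FALSE),
    mediating_targets = list(.data$modulator),
    .groups = "drop")
}

#' Infer the MRE-mediated miRNA-miRNA network
#'
#' Full inference: enumerate candidate triplets from the target network,
#' score each with the modulation statistic and a permutation p-value,
#' combine triplet p-values per miRNA pair with Fisher's method, and keep
#' pairs with combined p below `alpha` as undirected network edges.
#'
#' The default threshold `alpha = exp(-5)` (about 6.7e-3) takes the
#' significance cutoff literally on the natural scale; pass `alpha = 1e-5`
#' for the decimal reading. No multiplicity correction is applied by default
#' (`adjust = "BH"` switches the threshold to Benjamini-Hochberg-adjusted
#' p-values).
#'
#' @inheritParams score_triplets
#' @inheritParams enumerate_candidates
#' @param alpha Significance threshold on the combined p-value.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `mirna_network` whose edges carry `x2`, `dof`, `combined_p` and
#'   `n_targets`, and which retains the full `pairs` and `triplets` tables.
#' @export
infer_network <- function(mir, mrna, targets, alpha = exp(-5), n_perm = 1000,
                          bins_marginal = 3, bins_conditional = 3, strata = 2,
                          seed = 0, strict = FALSE,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha <= 1)
  if (!identical(colnames(mir), colnames(mrna))) {
    stop("matrices must be sample-aligned; see align_samples()")
  }
  cand <- enumerate_candidates(targets, mir, mrna, strict = strict)
  trip <- score_triplets(cand, mir, mrna, n_perm = n_perm, seed = seed,
                         bins_marginal = bins_marginal,
                         bins_conditional = bins_conditional, strata = strata)
  pairs <- combine_pairs(trip)
  crit <- if (adjust == "BH") p.adjust(pairs$combined_p, "BH") else pairs$combined_p
  keep <- crit < alpha
  edges <- pairs[keep, c("mir_a", "mir_b", "x2", "dof", "combined_p",
                         "n_targets")]
  if (nrow(edges) == 0L) {
    warning("no pair passed the significance threshold: empty network")
  }
  mirna_network(edges, nodes = union(edges$mir_a, edges$mir_b),
                relation = "mre", pairs = pairs, triplets = trip,
                params = list(alpha = alpha, n_perm = n_perm,
                              bins_marginal = bins_marginal,
                              bins_conditional = bins_conditional,
                              strata = strata, seed = seed, strict = strict,
                              adjust = adjust))
}
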