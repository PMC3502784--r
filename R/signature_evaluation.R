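#' Cross-validated classifier accuracy of a miRNA signature
#'
#' Trains a maximum-margin linear classifier (linear-kernel SVM, default
#' regularization) on the signature's expression rows only and reports
#' accuracy under stratified k-fold cross-validation. Folds are stratified by
#' class and fixed by `seed`, so repeated calls reproduce exactly.
#'
#' @param expr Expression matrix (features x samples).
#' @param labels Binary class per sample (factor, character or logical),
#'   length `ncol(expr)`; both classes must be present.
#' @param signature Character vector of feature ids to train on.
#' @param cv_folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return Cross-validated accuracy in `[0, 1]`.
#' @export
classifier_accuracy <- function(expr, labels, signature, cv_folds = 5,
                                seed = 0) {
  expr <- validate_expression(expr)
  labels <- factor(labels)
  stopifnot(length(labels) == ncol(expr))
  if (nlevels(labels) != 2L) stop("labels must contain exactly two classes")
  missing_ids <- setdiff(signature, rownames(expr))
  if (length(missing_ids) > 0L) {
    stop("signature ids not in matrix: ", paste(missing_ids, collapse = ", "))
  }
  x <- t(expr[signature, , drop = FALSE])
  folds <- stratified_folds(labels, cv_folds, seed)
  correct <- logical(length(labels))
  for (f in seq_len(cv_folds)) {
    test <- folds == f
    fit <- e1071::svm(x[!test, , drop = FALSE], labels[!test],
                      kernel = "linear", scale = FALSE)
    correct[test] <- predict(fit, x[test, , drop = FALSE]) == labels[test]
  }
  mean(correct)
}

stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Random-signature null for classifier accuracy
#'
#' Measures whether a signature's classification accuracy is special: draws
#' `n_lists` uniform random size-`k` subsets of all features, computes the
#' same cross-validated accuracy for each, and reports the pseudocount
#' empirical p-value
#' `(1 + #\{null >= signature\}) / (n_lists + 1)`.
#'
#' @inheritParams classifier_accuracy
#' @param k Random signature size (defaults to `length(signature)`).
#' @param n_lists Number of random signatures (default 1000).
#' @return A list of class `classifier_null`: `signature_accuracy`,
#'   `null_accuracies`, `null_mean_accuracy`, `empirical_p`.
#' @export
random_signature_null <- function(expr, labels, signature,
                                  k = length(signature), n_lists = 1000,
                                  cv_folds = 5, seed = 0) {
  if (n_lists < 1L) stop("n_lists must be at least 1")
  expr <- validate_expression(expr)
  if (nrow(expr) < k) stop("fewer features than the signature size")
  sig_acc <- classifier_accuracy(expr, labels, signature, cv_folds, seed)
  lists <- withr::with_seed(seed, {
    replicate(n_lists, sample(rownames(expr), k), simplify = FALSE)
  })
  null_acc <- vapply(seq_along(lists), function(i) {
    classifier_accuracy(expr, labels, lists[[i]], cv_folds, seed)
  }, numeric(1))
  structure(list(signature_accuracy = sig_acc, null_accuracies = null_acc,
                 null_mean_accuracy = mean(null_acc),
                 empirical_p = (1 + sum(null_acc >= sig_acc)) / (n_lists + 1),
                 n_lists = as.integer(n_lists)),
            class = "classifier_null")
}

#' @export
print.classifier_null <- function(x, ...) {
  cat(sprintf("signature accuracy %.3f vs random-signature mean %.3f (n = %d), empirical p = %.4g\n",
              x$signature_accuracy, x$null_mean_accuracy, x$n_lists,
              x$empirical_p))
  invisible(x)
}

#' @export
glance.classifier_null <- function(x, ...) {
  tibble::tibble(signature_accuracy = x$signature_accuracy,
                 null_mean_accuracy = x$null_mean_accuracy,
                 empirical_p = x$empirical_p, n_lists = x$n_lists)
}

#' @export
tidy.classifier_null <- function(x, ...) {
  tibble::tibble(list = seq_along(x$null_accuracies),
                 accuracy = x$null_accuracies)
}

#' Principal-component view of samples on a signature
#'
#' PCA of the signature-restricted, feature-centered matrix. Component signs
#' are fixed by making each component's largest-magnitude loading positive,
#' so coordinates are deterministic.
#'
#' @inheritParams classifier_accuracy
#' @param n_components Number of components to keep (default 3).
#' @return A list of class `pca_view`: `scores` (tibble `sample_id`, `PC1`,
#'   ...), `explained_variance` (proportions), `loadings`.
#' @export
pca_view <- function(expr, signature, n_components = 3) {
  expr <- validate_expression(expr)
  if (length(signature) < 3L) stop("need at least 3 signature features")
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  x <- t(expr[signature, , drop = FALSE])
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(fit$rotation))
  rot <- fit$rotation[, seq_len(n_components), drop = FALSE]
  sco <- fit$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  scores <- tibble::as_tibble(sco)
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(expr)), scores)
  structure(list(scores = scores,
                 explained_variance = (fit$sdev^2 / sum(fit$sdev^2))[seq_len(n_components)],
                 loadings = rot),
            class = "pca_view")
}

#' Cluster samples on a signature
#'
#' @inheritParams classifier_accuracy
#' @param method `"kmeans"` (50 restarts, seed-fixed) or `"hierarchical"`
#'   (average linkage on Euclidean distance, cut to `n_groups`).
#' @param n_groups Number of groups (default 2).
#' @return A tibble with `sample_id` and integer `group`.
#' @export
cluster_samples <- function(expr, signature, method = c("kmeans", "hierarchical"),
                            n_groups = 2, seed = 0) {
  method <- match.arg(method)
  expr <- validate_expression(expr)
  if (n_groups > ncol(expr)) stop("more groups than samples")
  if (n_groups < 2L) stop("need at least 2 groups")
  x <- t(expr[signature, , drop = FALSE])
  group <- if (method == "kmeans") {
    withr::with_seed(seed, kmeans(x, centers = n_groups, nstart = 50)$cluster)
  } else {
    cutree(hclust(dist(x), method = "average"), k = n_groups)
  }
  tibble::tibble(sample_id = colnames(expr), group = as.integer(group))
}

#' Survival analysis of a miRNA signature
#'
#' Prognostic evaluation: (i) split samples into two risk groups by k-means
#' on the signature rows, labelling the group with lower mean signature
#' expression `"low"`; (ii) Kaplan-Meier curves per group; (iii) log-rank
#' test; (iv) Cox proportional-hazards fit of the group indicator giving a
#' hazard ratio (low- versus high-expression group) with a Wald 95% CI; (v)
#' univariate per-miRNA and multivariate Cox coefficients over the
#' signature.
#'
#' @inheritParams classifier_accuracy
#' @param meta Metadata tibble with `sample_id`, `time_to_event`,
#'   `event_flag`; at least 10 events required.
#' @return A list of class `signature_survival` with `groups` (tibble),
#'   `km` (a `survfit`), `logrank_p`, `hazard_ratio`, `hr_ci` (length-2),
#'   `cox_group` (the group-model `coxph`), `univariate` and `multivariate`
#'   coefficient tibbles, and `multivariate_converged`.
#' @export
survival_analysis <- function(expr, signature, meta, seed = 0) {
  expr <- validate_expression(expr)
  meta <- validate_metadata(meta)
  if (!all(c("time_to_event", "event_flag") %in% names(meta))) {
    stop("metadata must carry time_to_event and event_flag")
  }
  common <- intersect(colnames(expr), meta$sample_id)
  expr <- expr[, common, drop = FALSE]
  meta <- meta[match(common, meta$sample_id), , drop = FALSE]
  if (sum(meta$event_flag) < 10L) stop("fewer than 10 events")
  if (any(meta$time_to_event <= 0)) stop("degenerate input: nonpositive event times")

  cl <- cluster_samples(expr, signature, method = "kmeans", n_groups = 2,
                        seed = seed)
  mean_sig <- colMeans(expr[signature, , drop = FALSE])
  grp_means <- tapply(mean_sig, cl$group, mean)
  low_group <- as.integer(names(grp_means)[which.min(grp_means)])
  groups <- tibble::tibble(sample_id = cl$sample_id,
                           group = ifelse(cl$group == low_group, "low", "high"))
  if (length(unique(groups$group)) < 2L) stop("risk grouping is degenerate")

  surv <- survival::Surv(meta$time_to_event, meta$event_flag)
  gf <- factor(groups$group, levels = c("high", "low"))
  km <- survival::survfit(surv ~ gf)
  lr <- survival::survdiff(surv ~ gf)
  logrank_p <- pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  cox <- survival::coxph(surv ~ gf)
  beta <- unname(cox$coefficients[1L])
  se <- sqrt(unname(diag(cox$var))[1L])
  hr <- exp(beta)
  ci <- exp(beta + c(-1, 1) * 1.96 * se)

  uni <- purrr::map_dfr(signature, function(id) {
    fit <- survival::coxph(surv ~ expr[id, ])
    s <- summary(fit)
    tibble::tibble(mirna = id, coefficient = unname(fit$coefficients[1L]),
                   hazard_ratio = unname(s$conf.int[1L, "exp(coef)"]),
                   hr_low = unname(s$conf.int[1L, "lower .95"]),
                   hr_high = unname(s$conf.int[1L, "upper .95"]),
                   p_value = unname(s$coefficients[1L, "Pr(>|z|)"]))
  })
  multi_converged <- TRUE
  xm <- t(expr[signature, , drop = FALSE])
  multi_fit <- withCallingHandlers(
    survival::coxph(surv ~ xm),
    warning = function(w) {
      multi_converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  multi <- tibble::tibble(mirna = signature,
                          coefficient = unname(multi_fit$coefficients))

  structure(list(groups = groups, km = km, logrank_p = logrank_p,
                 hazard_ratio = hr, hr_ci = ci, cox_group = cox,
                 univariate = uni, multivariate = multi,
                 multivariate_converged = multi_converged,
                 n_events = sum(meta$event_flag)),
            class = "signature_survival")
}

#' @export
print.signature_survival <- function(x, ...) {
  cat(sprintf("risk groups (low vs high signature expression): HR %.2f (95%% CI %.2f-%.2f), log-rank p = %.3g, %d events\n",
              x$hazard_ratio, x$hr_ci[1L], x$hr_ci[2L], x$logrank_p,
              x$n_events))
  invisible(x)
}

#' @export
glance.signature_survival <- function(x, ...) {
  tibble::tibble(hazard_ratio = x$hazard_ratio, hr_low = x$hr_ci[1L],
                 hr_high = x$hr_ci[2L], logrank_p = x$logrank_p,
                 n_events = x$n_events,
                 multivariate_converged = x$multivariate_converged)
}

#' @export
tidy.signature_survival <- function(x, ...) {
  dplyr::left_join(x$univariate,
                   dplyr::rename(x$multivariate,
                                 multivariate_coefficient = "coefficient"),
                   by = "mirna")
}

#' Fold-change differential expression with a permutation test
#'
#' Per-feature fold change between two classes plus a label-permutation
#' p-value on the absolute mean difference and Benjamini-Hochberg q-values.
#' Fold change is `mean(class1) / mean(class0)` on positive-scale data; for
#' log2-scale input set `log_scale = TRUE` and values are exponentiated
#' first (the fold change is then `2^(mean difference)`).
#'
#' @inheritParams classifier_accuracy
#' @param log_scale Input is log2-scale (default `FALSE`).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Seed for the permutations.
#' @return A tibble with `feature_id`, `mean_class0`, `mean_class1`,
#'   `fold_change`, `p_value`, `q_value`. Class 0/1 follow the factor level
#'   order of `labels`.
#' @export
differential_expression <- function(expr, labels, log_scale = FALSE,
                                    n_perm = 1000, seed = 0) {
  expr <- validate_expression(expr)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must contain exactly two classes")
  if (min(table(labels)) < 3L) stop("each class needs at least 3 samples")
  x <- if (log_scale) 2^expr else expr
  is1 <- labels == levels(labels)[2L]
  m0 <- unname(rowMeans(x[, !is1, drop = FALSE]))
  m1 <- unname(rowMeans(x[, is1, drop = FALSE]))
  if (!log_scale && any(c(m0, m1) <= 0)) {
    stop("nonpositive class means: if the data are log-scale, set log_scale = TRUE")
  }
  obs <- abs(m1 - m0)
  count <- integer(nrow(x))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample(is1)
      d <- abs(rowMeans(x[, perm, drop = FALSE]) -
                 rowMeans(x[, !perm, drop = FALSE]))
      count <- count + (d >= obs)
    }
  })
  p <- (1 + count) / (n_perm + 1)
  tibble::tibble(feature_id = rownames(expr), mean_class0 = m0,
                 mean_class1 = m1, fold_change = m1 / m0, p_value = p,
                 q_value = p.adjust(p, "BH"))
}
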