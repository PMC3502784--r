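two_class_expr <- function(n_features = 30, n_per_class = 25, shift = 5,
                           sig_rows = 1:5, seed = 13) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n_features * n), n_features, n,
              dimnames = list(sprintf("miR-%d", seq_len(n_features)),
                              sprintf("S%02d", seq_len(n))))
  labels <- rep(c("normal", "tumor"), each = n_per_class)
  x[sig_rows, labels == "tumor"] <- x[sig_rows, labels == "tumor"] + shift
  list(expr = x, labels = labels, signature = rownames(x)[sig_rows])
}

test_that("classifier accuracy separates planted classes and not noise", {
  d <- two_class_expr(shift = 5)
  acc <- classifier_accuracy(d$expr, d$labels, d$signature, seed = 1)
  expect_gte(acc, 0.95)

  # no-signal signature: accuracy near the majority-class rate
  noise_sig <- rownames(d$expr)[10:14]
  acc0 <- classifier_accuracy(d$expr, d$labels, noise_sig, seed = 1)
  expect_lte(acc0, 0.75)

  # invariant to feature order within the signature
  expect_identical(acc,
                   classifier_accuracy(d$expr, d$labels, rev(d$signature),
                                       seed = 1))
  expect_error(classifier_accuracy(d$expr, rep("a", ncol(d$expr)),
                                   d$signature), "two classes")
})

test_that("the random-signature null detects planted signatures at the floor", {
  # moderate per-row signal, large feature pool: a random subset catching one
  # signal row cannot match the 5-row signature
  d <- two_class_expr(n_features = 200, n_per_class = 30, shift = 2)
  res <- random_signature_null(d$expr, d$labels, d$signature, n_lists = 30,
                               seed = 2)
  expect_equal(res$empirical_p, 1 / 31, tolerance = 1e-12)
  expect_gt(res$signature_accuracy, res$null_mean_accuracy)

  # signature indistinguishable from the null: p forced to 1 when beaten
  d2 <- two_class_expr(n_features = 10, shift = 5, sig_rows = 1:8)
  res2 <- random_signature_null(d2$expr, d2$labels,
                                rownames(d2$expr)[9:10], k = 8,
                                n_lists = 1, seed = 3)
  expect_equal(res2$empirical_p, 1)
  expect_error(random_signature_null(d$expr, d$labels, d$signature,
                                     n_lists = 0), "at least 1")
})

test_that("PCA view is deterministic, sign-fixed and captures planted structure", {
  d <- two_class_expr(n_features = 12, sig_rows = 1:6, shift = 4)
  pv <- pca_view(d$expr, d$signature)
  expect_identical(pv$scores, pca_view(d$expr, d$signature)$scores)
  # classes separate on PC1 beyond the within-class spread
  pc1 <- pv$scores$PC1
  between <- abs(mean(pc1[d$labels == "tumor"]) - mean(pc1[d$labels == "normal"]))
  within <- max(sd(pc1[d$labels == "tumor"]), sd(pc1[d$labels == "normal"]))
  expect_gt(between, within)

  # rank-1 matrix: first component carries essentially all variance
  u <- rnorm(10)
  v <- rnorm(20)
  x1 <- outer(u, v)
  dimnames(x1) <- list(sprintf("f%d", 1:10), sprintf("S%d", 1:20))
  pv1 <- pca_view(x1, rownames(x1))
  expect_gt(pv1$explained_variance[1], 0.999)

  # duplicated samples land on identical coordinates
  xd <- d$expr
  xd[, 2] <- xd[, 1]
  pvd <- pca_view(xd, d$signature)
  expect_equal(unlist(pvd$scores[1, -1]), unlist(pvd$scores[2, -1]),
               tolerance = 1e-12)
})

test_that("clustering recovers planted groups up to label permutation", {
  d <- two_class_expr(n_features = 12, sig_rows = 1:6, shift = 6)
  truth <- as.integer(factor(d$labels))
  for (method in c("kmeans", "hierarchical")) {
    cl <- cluster_samples(d$expr, d$signature, method = method, n_groups = 2,
                          seed = 4)
    agree <- max(mean(cl$group == truth), mean(cl$group == 3 - truth))
    expect_gte(agree, 0.95)
  }
  # three planted groups
  set.seed(15)
  centers <- c(-6, 0, 6)
  x3 <- sapply(rep(centers, each = 20), function(mu) rnorm(5, mu))
  dimnames(x3) <- list(sprintf("f%d", 1:5), sprintf("S%02d", 1:60))
  cl3 <- cluster_samples(x3, rownames(x3), method = "kmeans", n_groups = 3,
                         seed = 4)
  truth3 <- rep(1:3, each = 20)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  agree3 <- max(vapply(perms, function(p) mean(p[cl3$group] == truth3),
                       numeric(1)))
  expect_gte(agree3, 0.9)
  expect_error(cluster_samples(d$expr, d$signature, n_groups = 100), "groups")
})

test_that("survival analysis recovers a planted hazard split", {
  sim <- simulate_dataset(simulation_config(
    n_mirnas = 15, n_mrnas = 5, n_true_triplets = 0, n_null_triplets = 0,
    hub_triplets = 0, n_decoy_edges = 0, hazard_ratio = 4.9, seed = 7))
  res <- survival_analysis(sim$mir, sim$signature, sim$meta, seed = 7)
  expect_gt(res$hazard_ratio, 1)
  expect_lt(res$logrank_p, 0.01)
  # k-means risk groups align with the generator's latent risk labels
  truth <- sim$meta$risk_group[match(res$groups$sample_id, sim$meta$sample_id)]
  agree <- max(mean((res$groups$group == "low") == (truth == "high")),
               mean((res$groups$group == "low") == (truth == "low")))
  expect_gte(agree, 0.9)
  expect_equal(nrow(res$univariate), 11)
  expect_equal(nrow(res$multivariate), 11)

  # degenerate inputs are rejected
  meta0 <- sim$meta
  meta0$event_flag <- FALSE
  expect_error(survival_analysis(sim$mir, sim$signature, meta0, seed = 7),
               "events")
  meta1 <- sim$meta
  meta1$time_to_event <- 0
  expect_error(survival_analysis(sim$mir, sim$signature, meta1, seed = 7),
               "degenerate|events")
})

test_that("fold-change differential expression matches exact constructions", {
  set.seed(23)
  base <- matrix(rexp(20 * 10) + 1, 20, 10,
                 dimnames = list(sprintf("f%d", 1:20), sprintf("A%d", 1:10)))
  x <- cbind(base, base * 0.5)
  colnames(x) <- sprintf("S%02d", 1:20)
  labels <- rep(c("c0", "c1"), each = 10)
  de <- differential_expression(x, labels, n_perm = 200, seed = 5)
  expect_equal(de$fold_change, rep(0.5, 20), tolerance = 1e-12)

  # identical class means: fold change exactly 1
  x2 <- cbind(base, base)
  colnames(x2) <- sprintf("S%02d", 1:20)
  de2 <- differential_expression(x2, labels, n_perm = 100, seed = 5)
  expect_equal(de2$fold_change, rep(1, 20), tolerance = 1e-12)

  # planted 2-fold down features rise to the top of the q-value list
  set.seed(24)
  noise <- matrix(rexp(30 * 40) + 2, 30, 40,
                  dimnames = list(sprintf("g%d", 1:30), sprintf("S%02d", 1:40)))
  lab <- rep(c("c0", "c1"), each = 20)
  noise[1:5, lab == "c1"] <- noise[1:5, lab == "c1"] * 0.5
  de3 <- differential_expression(noise, lab, n_perm = 500, seed = 6)
  hits <- de3$feature_id[de3$q_value < 0.1]
  expect_true(all(sprintf("g%d", 1:5) %in% hits))

  neg <- matrix(rnorm(20), 2, 10,
                dimnames = list(c("a", "b"), sprintf("S%d", 1:10)))
  expect_error(differential_expression(neg, rep(c("x", "y"), each = 5)),
               "log_scale")
})
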