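star_net <- function(n_leaves = 10) {
  mirna_network(tibble::tibble(mir_a = "hub",
                               mir_b = sprintf("leaf%02d", seq_len(n_leaves))))
}

test_that("hub report reproduces closed-form degree structure", {
  hr <- hub_report(star_net(10), k = 3)
  top <- hr$nodes[1, ]
  expect_identical(top$mirna, "hub")
  expect_equal(top$degree, 10)
  expect_equal(top$fraction, 1)
  expect_true(all(hr$nodes$fraction[-1] == 0.1))
  expect_equal(hr$summary$mean_degree, 20 / 11)

  tri <- mirna_network(tibble::tibble(mir_a = c("a", "b", "a"),
                                      mir_b = c("b", "c", "c")))
  hrt <- hub_report(tri)
  expect_equal(hrt$summary$mean_degree, 2)
  expect_equal(hrt$summary$min_degree, 2)
  expect_equal(hrt$summary$max_degree, 2)
  expect_error(hub_report(mirna_network(
    tibble::tibble(mir_a = character(), mir_b = character()))), "empty")
})

test_that("networks are undirected, deduplicated and self-loop-free", {
  net <- mirna_network(tibble::tibble(mir_a = c("b", "a", "a"),
                                      mir_b = c("a", "b", "c")))
  expect_equal(nrow(net$edges), 2)
  expect_true(all(net$edges$mir_a < net$edges$mir_b))
  expect_error(mirna_network(tibble::tibble(mir_a = "a", mir_b = "a")),
               "self-loop")
})

test_that("shared-target significance matches the exact hypergeometric tail", {
  # identical 10-target sets drawn from a 20-mRNA urn
  genes <- sprintf("G%02d", 1:20)
  edges <- rbind(data.frame(m = "miR-1", g = genes[1:10]),
                 data.frame(m = "miR-2", g = genes[1:10]),
                 data.frame(m = "miR-3", g = genes[11:20]))
  net <- shared_target_network(target_network(edges), alpha = 0.05)
  p12 <- net$pairs[net$pairs$mir_a == "miR-1" & net$pairs$mir_b == "miR-2", ]
  expect_equal(p12$shared, 10)
  expect_equal(p12$p_value, oracle_hyper_tail(10, 10, 10, 20), tolerance = 1e-12)
  expect_true(pair_key("miR-1", "miR-2") %in%
                pair_key(net$edges$mir_a, net$edges$mir_b))
  # disjoint target sets: no edge at any alpha < 1
  p13 <- net$pairs[net$pairs$mir_a == "miR-1" & net$pairs$mir_b == "miR-3", ]
  expect_equal(p13$shared, 0)
  expect_equal(p13$p_value, 1, tolerance = 1e-12)

  # a miRNA targeting the whole urn shares everything with everyone: p = 1
  edges2 <- rbind(data.frame(m = "miR-all", g = genes),
                  data.frame(m = "miR-2", g = genes[1:5]))
  net2 <- shared_target_network(target_network(edges2), alpha = 0.5)
  expect_equal(net2$pairs$p_value, 1, tolerance = 1e-12)

  # randomised oracle check on small urns; an extra miRNA covering every
  # gene pins the urn (distinct target mRNAs in the network) to `urn`
  set.seed(21)
  for (rep in 1:20) {
    urn <- sample(10:30, 1)
    na <- sample(2:urn, 1)
    nb <- sample(2:urn, 1)
    g <- sprintf("G%02d", seq_len(urn))
    e <- rbind(data.frame(m = "A", g = sample(g, na)),
               data.frame(m = "B", g = sample(g, nb)),
               data.frame(m = "Z", g = g))
    pr <- shared_target_network(target_network(e), alpha = 1e-9)$pairs
    ab <- pr[pr$mir_a == "A" & pr$mir_b == "B", ]
    expect_equal(ab$p_value,
                 oracle_hyper_tail(ab$shared, na, nb, urn), tolerance = 1e-12)
  }
})

test_that("correlation network flags perfect and anti-correlated pairs only", {
  set.seed(31)
  x <- matrix(rnorm(20 * 30), 20, 30,
              dimnames = list(sprintf("miR-%d", 1:20), sprintf("S%d", 1:30)))
  x["miR-2", ] <- x["miR-1", ]          # duplicated row
  x["miR-3", ] <- -x["miR-1", ]         # perfect anti-correlation
  net <- correlation_network(x, alpha = 0.05)
  keys <- pair_key(net$edges$mir_a, net$edges$mir_b)
  expect_true(pair_key("miR-1", "miR-2") %in% keys)
  expect_true(pair_key("miR-1", "miR-3") %in% keys)

  # independent rows: BH at 0.05 yields at most a trifle of false edges
  y <- matrix(rnorm(40 * 50), 40, 50,
              dimnames = list(sprintf("m%d", 1:40), sprintf("S%d", 1:50)))
  net0 <- correlation_network(y, alpha = 0.05)
  expect_lte(nrow(net0$edges), 5)

  y <- rbind(y, constant = 1)
  rownames(y)[41] <- "const"
  expect_warning(correlation_network(y), "constant")
})

test_that("network comparison reports identity, disjointness and hub deltas", {
  a <- star_net(6)
  cmp_same <- compare_networks(a, a)
  expect_equal(cmp_same$jaccard, 1)
  expect_equal(cmp_same$degree_rank_correlation, 1)
  expect_length(cmp_same$hubs_a_not_b, 0)

  b <- mirna_network(tibble::tibble(mir_a = "x", mir_b = "y"))
  expect_equal(compare_networks(a, b)$jaccard, 0)
})

test_that("the shared-target comparator never sees expression data", {
  expect_false("mir" %in% names(formals(shared_target_network)))
  expect_false("expr" %in% names(formals(shared_target_network)))
  # and is a pure function of the target table
  genes <- sprintf("G%02d", 1:15)
  set.seed(41)
  e <- rbind(data.frame(m = "A", g = sample(genes, 6)),
             data.frame(m = "B", g = sample(genes, 7)),
             data.frame(m = "C", g = sample(genes, 5)))
  t1 <- shared_target_network(target_network(e))
  t2 <- shared_target_network(target_network(e))
  expect_identical(t1$edges, t2$edges)
})
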