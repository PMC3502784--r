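test_that("permutation p-values obey the pseudocount rule and dominate on XOR", {
  fx <- make_xor_fixture(25)
  for (seed in c(0, 1, 99)) {
    res <- permutation_p(fx$mir_a, fx$mir_b, fx$m, n_perm = 1000, seed = seed,
                         bins_marginal = 2, bins_conditional = 2, strata = 2)
    expect_equal(res$p_value, 1 / 1001, tolerance = 1e-12)
  }
  # identical inputs, identical stream -> identical result
  r1 <- permutation_p(fx$mir_a, fx$mir_b, fx$m, n_perm = 200, seed = 5)
  r2 <- permutation_p(fx$mir_a, fx$mir_b, fx$m, n_perm = 200, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  # p can never be 0 or exceed 1
  expect_gte(r1$p_value, 1 / 201)
  expect_lte(r1$p_value, 1)
})

test_that("candidate enumeration follows the target network and drops unresolvables", {
  mir <- matrix(rnorm(30), 3, 10,
                dimnames = list(c("miR-1", "miR-2", "miR-3"), sprintf("S%d", 1:10)))
  mrna <- matrix(rnorm(20), 2, 10,
                 dimnames = list(c("GENE1", "GENE2"), sprintf("S%d", 1:10)))
  net <- target_network(data.frame(m = "miR-1", g = "GENE1"))
  cand <- enumerate_candidates(net, mir, mrna)
  expect_equal(nrow(cand), 2)
  expect_setequal(cand$mir_b, c("miR-2", "miR-3"))

  # two edges sharing a modulator: matches brute-force enumeration
  net2 <- target_network(data.frame(m = c("miR-1", "miR-2"),
                                    g = c("GENE1", "GENE1")))
  cand2 <- enumerate_candidates(net2, mir, mrna)
  brute <- unique(do.call(rbind, lapply(c("miR-1", "miR-2"), function(a) {
    do.call(rbind, lapply(setdiff(rownames(mir), a), function(b) {
      data.frame(mir_a = min(a, b), mir_b = max(a, b), modulator = "GENE1")
    }))
  })))
  expect_setequal(paste(cand2$mir_a, cand2$mir_b, cand2$modulator),
                  paste(brute$mir_a, brute$mir_b, brute$modulator))

  # an edge whose mRNA is absent from the matrix is skipped with a message
  net3 <- target_network(data.frame(m = c("miR-1", "miR-1"),
                                    g = c("GENE1", "ABSENT")))
  expect_message(cand3 <- enumerate_candidates(net3, mir, mrna), "dropped 1")
  expect_equal(nrow(cand3), 2)
  expect_error(suppressMessages(
    enumerate_candidates(target_network(data.frame(m = "miR-9", g = "GENE1")),
                         mir, mrna)),
    "no resolvable")
})

test_that("strict mode requires the modulator to be targeted by both miRNAs", {
  mir <- matrix(rnorm(30), 3, 10,
                dimnames = list(c("miR-1", "miR-2", "miR-3"), sprintf("S%d", 1:10)))
  mrna <- matrix(rnorm(10), 1, 10, dimnames = list("GENE1", sprintf("S%d", 1:10)))
  net <- target_network(data.frame(m = c("miR-1", "miR-2"),
                                   g = c("GENE1", "GENE1")))
  strict <- enumerate_candidates(net, mir, mrna, strict = TRUE)
  expect_equal(nrow(strict), 1)
  expect_identical(strict$mir_a, "miR-1")
  expect_identical(strict$mir_b, "miR-2")
})

test_that("Fisher's method matches its closed forms and rejects invalid input", {
  res <- fisher_combine(c(0.5, 0.5))
  expect_equal(res$x2, -2 * (log(0.5) + log(0.5)), tolerance = 1e-12)
  expect_equal(res$dof, 4)
  # chi-square survival at even dof: (1 + x/2) exp(-x/2)
  expect_equal(res$combined_p, (1 + res$x2 / 2) * exp(-res$x2 / 2),
               tolerance = 1e-12)
  expect_equal(res$combined_p, 0.5966, tolerance = 1e-4)

  expect_equal(fisher_combine(0.03)$combined_p, 0.03, tolerance = 1e-12)
  # p = 1 contributes nothing to the statistic
  expect_equal(fisher_combine(c(0.2, 1))$x2, fisher_combine(0.2)$x2 + 0,
               tolerance = 1e-12)
  expect_error(fisher_combine(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fisher_combine(1.2), "\\(0, 1\\]")
  expect_error(fisher_combine(numeric(0)), "at least one")
})

test_that("pair combination pools both orientations and obeys the X2 identity", {
  trip <- tibble::tibble(
    mir_a = c("miR-1", "miR-1", "miR-1", "miR-2"),
    mir_b = c("miR-2", "miR-2", "miR-3", "miR-3"),
    modulator = c("G1", "G2", "G1", "G3"),
    p_value = c(0.01, 0.2, 0.5, 0.04))
  pairs <- combine_pairs(trip)
  expect_equal(nrow(pairs), 3)
  p12 <- pairs[pairs$mir_a == "miR-1" & pairs$mir_b == "miR-2", ]
  expect_equal(p12$n_targets, 2)
  expect_equal(p12$dof, 4)
  expect_equal(p12$x2, -2 * sum(log(c(0.01, 0.2))), tolerance = 1e-12)
  expect_equal(p12$combined_p,
               pchisq(p12$x2, df = 4, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("triplet scores are independent of candidate row order", {
  sim <- simulate_dataset(simulation_config(
    n_mirnas = 130, n_mrnas = 70, n_true_triplets = 3, n_null_triplets = 2,
    hub_triplets = 2, n_decoy_edges = 3, n_samples = 80, seed = 4))
  cand <- suppressMessages(
    enumerate_candidates(sim$targets, sim$mir, sim$mrna))
  cand <- cand[1:20, ]
  fwd <- score_triplets(cand, sim$mir, sim$mrna, n_perm = 100, seed = 9)
  rev <- score_triplets(cand[rev(seq_len(nrow(cand))), ], sim$mir, sim$mrna,
                        n_perm = 100, seed = 9)
  rev <- rev[match(paste(fwd$mir_a, fwd$mir_b, fwd$modulator),
                   paste(rev$mir_a, rev$mir_b, rev$modulator)), ]
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-15)
})

test_that("the significance threshold acts monotonically on the edge set", {
  sim <- simulate_dataset(simulation_config(
    n_mirnas = 128, n_mrnas = 70, n_true_triplets = 2, n_null_triplets = 2,
    hub_triplets = 0, n_decoy_edges = 2, n_samples = 60, seed = 5))
  net <- suppressMessages(
    infer_network(sim$mir, sim$mrna, sim$targets, alpha = 0.01, n_perm = 200,
                  seed = 5))
  # alpha = 1 keeps every tested pair
  net_all <- suppressMessages(suppressWarnings(
    infer_network(sim$mir, sim$mrna, sim$targets, alpha = 1, n_perm = 200,
                  seed = 5)))
  # strict threshold: pairs with combined_p exactly 1 are the only exclusions
  expect_equal(nrow(net_all$edges), sum(net_all$pairs$combined_p < 1))
  expect_true(all(pair_key(net$edges$mir_a, net$edges$mir_b) %in%
                    pair_key(net_all$edges$mir_a, net_all$edges$mir_b)))
  # network edges carry the scores of their pair rows
  expect_true(all(net$edges$combined_p < 0.01))
})

test_that("type-I error is calibrated for independent triplets", {
  # modest-scale calibration: 150 null triplets at n = 60
  set.seed(8)
  ps <- vapply(seq_len(150), function(i) {
    permutation_p(rnorm(60), rnorm(60), rnorm(60), n_perm = 99, seed = i)$p_value
  }, numeric(1))
  rej <- mean(ps <= 0.05)
  ci <- qbinom(c(0.005, 0.995), 150, 0.05) / 150
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})
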