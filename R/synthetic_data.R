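#' Simulation configuration
#'
#' Parameters of the synthetic paired miRNA/mRNA cohort generator. Defaults
#' emulate the shape of a prostate-cohort study: 139 joint samples, 370
#' miRNAs, class proportions scaled from 29 normal / 98 primary / 19
#' metastatic, and a strong prognostic split (hazard ratio 4.9).
#'
#' Planted modulation follows a mixture-of-couplings mechanism: each true
#' triplet has a modulator mRNA drawn standard normal; samples above the
#' modulator's median form the "high" stratum and the miRNA pair is bivariate
#' normal with correlation `coupling_high` there and `coupling_low` below the
#' median. Planted null triplets use a common coupling (`null_coupling`) in
#' both strata, so they are correlated but not modulated. Small independent
#' Gaussian measurement noise (`noise_sd`) is added to every feature.
#'
#' @param n_samples Number of joint samples (default 139; minimum 20).
#' @param n_mirnas,n_mrnas Feature counts (defaults 370 and 1000; the mRNA
#'   side is a desk-scale stand-in for a genome-wide matrix).
#' @param n_true_triplets,n_null_triplets Planted modulated and planted null
#'   triplet counts (defaults 10 and 50).
#' @param coupling_high,coupling_low Pair correlation in the high/low
#'   modulator stratum of true triplets (defaults 0.9 and 0).
#' @param null_coupling Common-stratum correlation of planted nulls (0.5).
#' @param noise_sd Measurement noise standard deviation (default 0.1, small
#'   relative to the unit-variance signal so planted couplings survive).
#' @param hub_triplets Number of true triplets anchored on a single hub miRNA
#'   (default 8 of the 10), planting a high-degree node.
#' @param n_decoy_edges Random target edges attached to background miRNAs
#'   (default 30), giving the shared-target comparator non-trivial structure.
#' @param signature_size Size of the designated diagnostic/prognostic
#'   signature (default 11 background miRNAs).
#' @param class_shift Per-row mean shift of the diagnostic half of the
#'   signature in tumor versus normal samples (default -1.6 sd:
#'   downregulation in cancer; a planted factor of norm about 4 sd over the
#'   6 diagnostic rows).
#' @param risk_shift Per-row mean shift of the prognostic half of the
#'   signature in high-risk samples (default -3.6 sd: low expression marks
#'   aggressive disease; a planted factor of norm about 8 sd over the 5
#'   prognostic rows). The two shifts act on disjoint signature rows so the
#'   planted diagnostic and prognostic factors are separately identifiable.
#' @param baseline_hazard,hazard_ratio Exponential survival model: low-risk
#'   hazard and the high/low risk hazard ratio (defaults 0.05 and 4.9).
#' @param censor_max Administrative censoring horizon, uniform on
#'   `(0, censor_max)` (default 10; yields roughly 40% events).
#' @param class_counts Optional integer vector `c(normal, primary,
#'   metastatic)`; defaults to (29, 98, 19)/146 scaled to `n_samples` by
#'   largest remainder.
#' @param seed Integer seed fixing the full output bit-for-bit.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 139, n_mirnas = 370, n_mrnas = 1000,
                              n_true_triplets = 10, n_null_triplets = 50,
                              coupling_high = 0.9, coupling_low = 0,
                              null_coupling = 0.5, noise_sd = 0.1,
                              hub_triplets = 8, n_decoy_edges = 30,
                              signature_size = 11, class_shift = -1.6,
                              risk_shift = -3.6, baseline_hazard = 0.05,
                              hazard_ratio = 4.9, censor_max = 10,
                              class_counts = NULL, seed = 0) {
  cfg <- list(n_samples = as.integer(n_samples), n_mirnas = as.integer(n_mirnas),
              n_mrnas = as.integer(n_mrnas),
              n_true_triplets = as.integer(n_true_triplets),
              n_null_triplets = as.integer(n_null_triplets),
              coupling_high = coupling_high, coupling_low = coupling_low,
              null_coupling = null_coupling, noise_sd = noise_sd,
              hub_triplets = as.integer(hub_triplets),
              n_decoy_edges = as.integer(n_decoy_edges),
              signature_size = as.integer(signature_size),
              class_shift = class_shift, risk_shift = risk_shift,
              baseline_hazard = baseline_hazard, hazard_ratio = hazard_ratio,
              censor_max = censor_max, class_counts = class_counts,
              seed = as.integer(seed))
  if (cfg$n_samples < 20L) stop("n_samples < 20: modulator strata too small for conditional MI")
  stopifnot(cfg$n_mirnas > 0, cfg$n_mrnas > 0, cfg$n_true_triplets >= 0,
            cfg$n_null_triplets >= 0, cfg$noise_sd >= 0,
            abs(coupling_high) <= 1, abs(coupling_low) <= 1,
            abs(null_coupling) <= 1, cfg$hub_triplets <= cfg$n_true_triplets,
            cfg$hazard_ratio > 0, cfg$baseline_hazard > 0, cfg$censor_max > 0)
  n_planted_mirna <- (cfg$n_true_triplets - cfg$hub_triplets) * 2L +
    cfg$hub_triplets + (cfg$hub_triplets > 0L) + cfg$n_null_triplets * 2L
  if (n_planted_mirna + cfg$signature_size > cfg$n_mirnas) {
    stop("n_mirnas too small for the planted triplets plus the signature")
  }
  if (cfg$n_true_triplets + cfg$n_null_triplets > cfg$n_mrnas) {
    stop("n_mrnas too small for one modulator per planted triplet")
  }
  structure(cfg, class = "simulation_config")
}

scale_class_counts <- function(n, counts = c(normal = 29, primary = 98,
                                             metastatic = 19)) {
  props <- counts / sum(counts)
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
  base[extra] <- base[extra] + 1
  stats::setNames(as.integer(base), names(counts))
}

#' Simulate a paired miRNA/mRNA cohort with planted modulation structure
#'
#' Generates a miRNA matrix, an mRNA matrix (same samples), a target network,
#' sample metadata (class labels, survival) and the planted ground truth, so
#' every downstream stage of the pipeline can be validated against known
#' structure. See [simulation_config()] for the generative model.
#'
#' The returned list also records the designated signature (background
#' miRNAs carrying the diagnostic and prognostic shifts) and the per-sample
#' latent risk group.
#'
#' @param config A [simulation_config()].
#' @return A list of class `mirmod_sim` with elements `mir`, `mrna`,
#'   `targets`, `meta`, `triplets` (tibble of planted triplets with their
#'   couplings and a `type` column), `signature`, `hub` and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    n <- cfg$n_samples
    samples <- sprintf("S%03d", seq_len(n))
    mirnas <- sprintf("miR-%d", seq_len(cfg$n_mirnas))
    mrnas <- sprintf("GENE%04d", seq_len(cfg$n_mrnas))

    # --- role bookkeeping -------------------------------------------------
    pool <- mirnas
    take <- function(k) {
      if (k == 0L) return(character(0))
      ids <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      ids
    }
    # The hub is planted as the shared *partner* of several anchored triplets:
    # each anchor miRNA carries exactly one target edge (anchor -> modulator),
    # so every planted pair is mediated by exactly one candidate triplet and
    # hub degree reflects detections, not Fisher pooling across a multi-target
    # anchor's unrelated edges.
    hub <- if (cfg$hub_triplets > 0L) take(1L) else character(0)
    hub_anchors <- take(cfg$hub_triplets)
    n_free <- cfg$n_true_triplets - cfg$hub_triplets
    free_a <- take(n_free)
    free_b <- take(n_free)
    null_a <- take(cfg$n_null_triplets)
    null_b <- take(cfg$n_null_triplets)
    signature <- take(cfg$signature_size)
    background <- pool

    trip <- tibble::tibble(
      mir_a = c(hub_anchors, free_a, null_a),
      mir_b = c(rep(hub, cfg$hub_triplets), free_b, null_b),
      modulator = mrnas[seq_len(cfg$n_true_triplets + cfg$n_null_triplets)],
      coupling_high = c(rep(cfg$coupling_high, cfg$n_true_triplets),
                        rep(cfg$null_coupling, cfg$n_null_triplets)),
      coupling_low = c(rep(cfg$coupling_low, cfg$n_true_triplets),
                       rep(cfg$null_coupling, cfg$n_null_triplets)),
      type = rep(c("true", "null"), c(cfg$n_true_triplets, cfg$n_null_triplets)))
    derived <- c(hub_anchors, free_b, null_b) # row rebuilt conditionally
    base <- c(rep(hub, cfg$hub_triplets), free_a, null_a)

    # --- expression -------------------------------------------------------
    mir <- matrix(rnorm(cfg$n_mirnas * n), nrow = cfg$n_mirnas,
                  dimnames = list(mirnas, samples))
    mrna <- matrix(rnorm(cfg$n_mrnas * n), nrow = cfg$n_mrnas,
                   dimnames = list(mrnas, samples))
    # one member of each planted pair keeps its fresh N(0,1) draw; the other
    # is rebuilt conditionally so the within-stratum correlation equals the
    # planted coupling (high stratum = modulator above its median)
    for (i in seq_len(nrow(trip))) {
      m <- mrna[trip$modulator[i], ]
      high <- m > median(m)
      a <- mir[base[i], ]
      rho <- ifelse(high, trip$coupling_high[i], trip$coupling_low[i])
      mir[derived[i], ] <- rho * a + sqrt(1 - rho^2) * rnorm(n)
    }

    # --- metadata ---------------------------------------------------------
    counts <- if (is.null(cfg$class_counts)) scale_class_counts(n) else cfg$class_counts
    class_label <- sample(rep(c("normal", "primary", "metastatic"), counts))
    risk <- rbinom(n, 1L, 0.5)
    lambda <- cfg$baseline_hazard * cfg$hazard_ratio^risk
    t_event <- rexp(n, rate = lambda)
    t_cens <- runif(n, 0, cfg$censor_max)
    meta <- tibble::tibble(sample_id = samples, class_label = class_label,
                           time_to_event = pmin(t_event, t_cens),
                           event_flag = t_event <= t_cens,
                           risk_group = ifelse(risk == 1L, "high", "low"))

    # diagnostic + prognostic structure on the designated signature: the first
    # half of the rows carries the tumor-vs-normal shift and the second half
    # the risk-group shift, so the two planted factors span orthogonal
    # directions and each is identifiable (collinear shifts would make the
    # classes linearly inseparable and contaminate the risk grouping)
    n_diag <- ceiling(length(signature) / 2)
    diag_rows <- signature[seq_len(n_diag)]
    prog_rows <- signature[-seq_len(n_diag)]
    tumor <- as.numeric(class_label != "normal")
    if (length(diag_rows) > 0L) {
      mir[diag_rows, ] <- mir[diag_rows, ] +
        matrix(cfg$class_shift * tumor, nrow = length(diag_rows), ncol = n,
               byrow = TRUE)
    }
    if (length(prog_rows) > 0L) {
      mir[prog_rows, ] <- mir[prog_rows, ] +
        matrix(cfg$risk_shift * risk, nrow = length(prog_rows), ncol = n,
               byrow = TRUE)
    }

    # measurement noise on everything
    mir <- mir + matrix(rnorm(length(mir), sd = cfg$noise_sd), nrow = nrow(mir))
    mrna <- mrna + matrix(rnorm(length(mrna), sd = cfg$noise_sd), nrow = nrow(mrna))

    # --- target network: planted edges (anchor -> modulator) plus decoys --
    planted <- tibble::tibble(mirna = trip$mir_a, mrna = trip$modulator)
    decoy_pool <- if (length(background) > 0L) background else mirnas
    decoys <- tibble::tibble(
      mirna = sample(decoy_pool, cfg$n_decoy_edges, replace = TRUE),
      mrna = sample(mrnas, cfg$n_decoy_edges, replace = TRUE))
    targets <- target_network(dplyr::distinct(dplyr::bind_rows(planted, decoys)),
                              source_tag = "synthetic")

    structure(list(mir = mir, mrna = mrna, targets = targets, meta = meta,
                   triplets = trip, signature = signature, hub = hub,
                   config = cfg),
              class = "mirmod_sim")
  })
}

#' @export
print.mirmod_sim <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d samples, %d miRNAs, %d mRNAs, %d planted triplets (%d true), %d target edges\n",
    ncol(x$mir), nrow(x$mir), nrow(x$mrna), nrow(x$triplets),
    sum(x$triplets$type == "true"), nrow(x$targets)))
  invisible(x)
}

#' Balanced XOR fixture for the modulation statistic
#'
#' The canonical worked example of modulation: two binary miRNAs that are
#' marginally independent but perfectly coupled within each modulator
#' stratum (`mir_b = mir_a` when `m = 0`, `mir_b = 1 - mir_a` when `m = 1`,
#' balanced cells). On the 2-bin / 2-stratum estimator this gives
#' `MI(a, b) = 0`, `MI(a, b | m) = log(2)` and `delta_MI = log(2)` exactly.
#'
#' @param n_per_cell Samples per (m, mir_a) cell; total n is `4 * n_per_cell`.
#' @return A list with numeric 0/1 vectors `mir_a`, `mir_b`, `m`.
#' @export
make_xor_fixture <- function(n_per_cell) {
  stopifnot(n_per_cell >= 1)
  m <- rep(c(0, 0, 1, 1), each = n_per_cell)
  a <- rep(c(0, 1, 0, 1), each = n_per_cell)
  b <- ifelse(m == 0, a, 1 - a)
  list(mir_a = as.numeric(a), mir_b = as.numeric(b), m = as.numeric(m))
}
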