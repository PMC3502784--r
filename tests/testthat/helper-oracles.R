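# Pure-R brute-force oracles, written independently of the package internals:
# nested loops over explicit contingency tables, no shared code with src/.

oracle_bins <- function(x, B) {
  n <- length(x)
  ord <- order(x, seq_along(x)) # stable: ties by original index
  sizes <- rep(n %/% B, B)
  if (n %% B > 0) sizes[seq_len(n %% B)] <- sizes[seq_len(n %% B)] + 1
  labels <- integer(n)
  labels[ord] <- rep(seq_len(B), sizes)
  labels
}

oracle_mi_from_labels <- function(xb, yb, B) {
  n <- length(xb)
  mi <- 0
  for (a in seq_len(B)) {
    for (b in seq_len(B)) {
      nij <- sum(xb == a & yb == b)
      if (nij > 0) {
        pij <- nij / n
        mi <- mi + pij * log(pij / ((sum(xb == a) / n) * (sum(yb == b) / n)))
      }
    }
  }
  mi
}

oracle_mi <- function(d, r, B) {
  oracle_mi_from_labels(oracle_bins(d, B), oracle_bins(r, B), B)
}

oracle_cmi <- function(d, r, m, B, S) {
  strat <- oracle_bins(m, S)
  n <- length(d)
  out <- 0
  for (s in seq_len(S)) {
    idx <- strat == s
    ns <- sum(idx)
    out <- out + (ns / n) * oracle_mi(d[idx], r[idx], B)
  }
  out
}

# exact hypergeometric upper tail by direct summation of choose() terms
oracle_hyper_tail <- function(shared, n_a, n_b, urn) {
  ks <- shared:min(n_a, n_b)
  sum(choose(n_a, ks) * choose(urn - n_a, n_b - ks)) / choose(urn, n_b)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
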