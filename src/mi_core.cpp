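#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// Equal-frequency binning with deterministic, stable tie handling: samples are
// ordered by value (ties kept in original index order) and split into B
// contiguous groups whose sizes differ by at most one; the first (n mod B)
// bins take the extra sample.
static std::vector<int> ef_bins(const std::vector<double>& x, int B) {
  const int n = (int)x.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return x[a] < x[b]; });
  if (x[ord[0]] == x[ord[n - 1]]) stop("zero-variance feature");
  std::vector<int> lab(n);
  const int base = n / B, extra = n % B;
  int pos = 0;
  for (int b = 0; b < B; ++b) {
    int sz = base + (b < extra ? 1 : 0);
    for (int k = 0; k < sz; ++k) lab[ord[pos++]] = b;
  }
  return lab;
}

static double mi_from_labels(const std::vector<int>& xb,
                             const std::vector<int>& yb, int Bx, int By) {
  const int n = (int)xb.size();
  std::vector<double> joint(Bx * By, 0.0), px(Bx, 0.0), py(By, 0.0);
  for (int i = 0; i < n; ++i) {
    joint[xb[i] * By + yb[i]] += 1.0;
    px[xb[i]] += 1.0;
    py[yb[i]] += 1.0;
  }
  double mi = 0.0;
  for (int a = 0; a < Bx; ++a)
    for (int b = 0; b < By; ++b) {
      double nij = joint[a * By + b];
      if (nij > 0.0) mi += (nij / n) * std::log(nij * n / (px[a] * py[b]));
    }
  return mi < 0.0 ? 0.0 : mi;
}

// Reusable scratch space for the conditional-MI evaluation so the hot
// permutation loop allocates nothing.
struct CmiScratch {
  std::vector<int> dbin, rbin, s_size, fill;
  std::vector<double> joint, px, py;
  CmiScratch(int n, int S, int B)
      : dbin(n), rbin(n), s_size(S), fill(S), joint(S * B * B), px(S * B),
        py(S * B) {}
};

// Conditional MI given precomputed stratum labels. Within each stratum the two
// vectors are re-binned at equal frequency using the global sort orders
// restricted to the stratum (O(n) passes, no re-sorting).
static double cmi_given_strata(const std::vector<int>& ord_d,
                               const std::vector<int>& ord_r,
                               const std::vector<int>& strat, int S, int B,
                               CmiScratch& sc) {
  const int n = (int)ord_d.size();
  std::fill(sc.s_size.begin(), sc.s_size.end(), 0);
  for (int i = 0; i < n; ++i) sc.s_size[strat[i]]++;
  // positions walked so far per stratum, reused for d then r
  std::fill(sc.fill.begin(), sc.fill.end(), 0);
  for (int k = 0; k < n; ++k) {
    int i = ord_d[k], s = strat[i];
    int ns = sc.s_size[s], base = ns / B, extra = ns % B;
    int p = sc.fill[s]++;
    int cut = (base + 1) * extra; // samples occupied by the first `extra` bins
    sc.dbin[i] = p < cut ? p / (base + 1) : extra + (p - cut) / base;
  }
  std::fill(sc.fill.begin(), sc.fill.end(), 0);
  for (int k = 0; k < n; ++k) {
    int i = ord_r[k], s = strat[i];
    int ns = sc.s_size[s], base = ns / B, extra = ns % B;
    int p = sc.fill[s]++;
    int cut = (base + 1) * extra;
    sc.rbin[i] = p < cut ? p / (base + 1) : extra + (p - cut) / base;
  }
  std::fill(sc.joint.begin(), sc.joint.end(), 0.0);
  std::fill(sc.px.begin(), sc.px.end(), 0.0);
  std::fill(sc.py.begin(), sc.py.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    int s = strat[i];
    sc.joint[(s * B + sc.dbin[i]) * B + sc.rbin[i]] += 1.0;
    sc.px[s * B + sc.dbin[i]] += 1.0;
    sc.py[s * B + sc.rbin[i]] += 1.0;
  }
  double cmi = 0.0;
  for (int s = 0; s < S; ++s) {
    int ns = sc.s_size[s];
    if (ns == 0) continue;
    double mis = 0.0;
    for (int a = 0; a < B; ++a)
      for (int b = 0; b < B; ++b) {
        double nij = sc.joint[(s * B + a) * B + b];
        if (nij > 0.0)
          mis += (nij / ns) *
                 std::log(nij * ns / (sc.px[s * B + a] * sc.py[s * B + b]));
      }
    if (mis > 0.0) cmi += (double)ns / n * mis;
  }
  return cmi;
}

// --- deterministic, platform-independent RNG -------------------------------
static uint64_t fnv1a64(const std::string& s) {
  uint64_t h = 1469598103934665603ULL;
  for (unsigned char c : s) {
    h ^= (uint64_t)c;
    h *= 1099511628211ULL;
  }
  return h;
}

struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, bound) without modulo bias
  uint64_t bounded(uint64_t bound) {
    uint64_t threshold = (-bound) % bound;
    for (;;) {
      uint64_t r = next();
      if (r >= threshold) return r % bound;
    }
  }
};

static std::vector<double> as_std(const NumericVector& x) {
  return std::vector<double>(x.begin(), x.end());
}

static std::vector<int> sort_order(const std::vector<double>& x) {
  std::vector<int> ord(x.size());
  for (size_t i = 0; i < x.size(); ++i) ord[i] = (int)i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return x[a] < x[b]; });
  return ord;
}

static void check_strata(const std::vector<int>& strat, int S, int B) {
  std::vector<int> sz(S, 0);
  for (int s : strat) sz[s]++;
  for (int s = 0; s < S; ++s)
    if (sz[s] < 2 * B)
      stop("stratum %d has %d samples; at least %d (2 x bins) required", s + 1,
           sz[s], 2 * B);
}

// [[Rcpp::export]]
IntegerVector cpp_discretize(NumericVector x, int B) {
  if (B < 2) stop("bin count must be at least 2");
  if ((int)x.size() < B) stop("need at least as many observations as bins");
  std::vector<int> lab = ef_bins(as_std(x), B);
  IntegerVector out(lab.size());
  for (size_t i = 0; i < lab.size(); ++i) out[i] = lab[i] + 1;
  return out;
}

// [[Rcpp::export]]
double cpp_mi(NumericVector d, NumericVector r, int B) {
  std::vector<int> db = ef_bins(as_std(d), B), rb = ef_bins(as_std(r), B);
  return mi_from_labels(db, rb, B, B);
}

// [[Rcpp::export]]
double cpp_cmi(NumericVector d, NumericVector r, NumericVector m, int B,
               int S) {
  std::vector<double> dd = as_std(d), rr = as_std(r);
  std::vector<int> strat = ef_bins(as_std(m), S);
  check_strata(strat, S, B);
  std::vector<int> ord_d = sort_order(dd), ord_r = sort_order(rr);
  CmiScratch sc((int)dd.size(), S, B);
  return cmi_given_strata(ord_d, ord_r, strat, S, B, sc);
}

// Permutation test for the modulation statistic |MI(d,r) - MI(d,r|m)|.
// Only the modulator is shuffled: the stratum assignment derived from m is
// permuted across samples, which for tie-free m is exactly a shuffle of m's
// values. The RNG stream is seeded from a hash of `key`, so p-values do not
// depend on the order in which triplets are evaluated.
// [[Rcpp::export]]
List cpp_permutation_delta(NumericVector d, NumericVector r, NumericVector m,
                           int b_marginal, int b_conditional, int S,
                           int n_perm, std::string key, bool return_null) {
  std::vector<double> dd = as_std(d), rr = as_std(r);
  const int n = (int)dd.size();
  std::vector<int> db = ef_bins(dd, b_marginal), rb = ef_bins(rr, b_marginal);
  double mi_marg = mi_from_labels(db, rb, b_marginal, b_marginal);

  std::vector<int> strat = ef_bins(as_std(m), S);
  check_strata(strat, S, b_conditional);
  std::vector<int> ord_d = sort_order(dd), ord_r = sort_order(rr);
  CmiScratch sc(n, S, b_conditional);
  double mi_cond = cmi_given_strata(ord_d, ord_r, strat, S, b_conditional, sc);
  double delta_obs = std::fabs(mi_marg - mi_cond);

  SplitMix64 rng(fnv1a64(key));
  std::vector<int> perm = strat;
  int n_ge = 0;
  NumericVector null_deltas(return_null ? n_perm : 0);
  for (int p = 0; p < n_perm; ++p) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)rng.bounded((uint64_t)(i + 1));
      std::swap(perm[i], perm[j]);
    }
    double cmi_p = cmi_given_strata(ord_d, ord_r, perm, S, b_conditional, sc);
    double delta_p = std::fabs(mi_marg - cmi_p);
    if (delta_p >= delta_obs) ++n_ge;
    if (return_null) null_deltas[p] = delta_p;
  }
  List out = List::create(
      _["mi_marginal"] = mi_marg, _["mi_conditional"] = mi_cond,
      _["delta_mi"] = delta_obs, _["n_ge"] = n_ge,
      _["p_value"] = (1.0 + n_ge) / (n_perm + 1.0));
  if (return_null) out["null_deltas"] = null_deltas;
  return out;
}
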