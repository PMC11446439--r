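#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic counter-free RNG stream (splitmix64). Each exported routine
// takes an integer seed so results are reproducible independently of R's RNG.
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline int rand_below(uint64_t &state, int n) {
  // modulo bias is < 2^-32 for the n used here (segment lengths)
  return (int)(splitmix64(state) % (uint64_t)n);
}

// type-7 quantile of a sorted vector
static double quantile7(const std::vector<double> &s, double p) {
  const int n = (int)s.size();
  if (n == 1) return s[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return s[n - 1];
  return s[lo] + (h - lo) * (s[lo + 1] - s[lo]);
}

// Quantile-based recurrence threshold grid from a random subsample of
// pairwise distances |x_i - x_j|.
static std::vector<double> eps_grid_from_distances(const double *x, int L,
                                                   int n_eps, double q_lo,
                                                   double q_hi, int n_pairs,
                                                   uint64_t &rng) {
  std::vector<double> d(n_pairs);
  for (int k = 0; k < n_pairs; ++k) {
    int i = rand_below(rng, L);
    int j = rand_below(rng, L);
    d[k] = std::fabs(x[i] - x[j]);
  }
  std::sort(d.begin(), d.end());
  std::vector<double> grid(n_eps);
  for (int e = 0; e < n_eps; ++e) {
    double p = (n_eps == 1) ? q_lo : q_lo + (q_hi - q_lo) * e / (n_eps - 1);
    grid[e] = quantile7(d, p);
  }
  return grid;
}

// Accumulate microstate counts for one segment over an ascending eps grid.
// counts is a dense [n_eps x 2^(N*N)] table (N <= 4); touched records which
// codes were hit so the table can be reset cheaply between segments.
struct DenseCounts {
  int n_eps, n_codes;
  std::vector<uint32_t> tab;
  std::vector<std::vector<uint32_t>> touched;
  DenseCounts(int E, int C) : n_eps(E), n_codes(C), tab((size_t)E * C, 0), touched(E) {}
  void reset() {
    for (int e = 0; e < n_eps; ++e) {
      for (uint32_t c : touched[e]) tab[(size_t)e * n_codes + c] = 0;
      touched[e].clear();
    }
  }
};

static void count_anchor_dense(const double *x, int i, int j, int N,
                               const std::vector<double> &eps, DenseCounts &dc) {
  const int E = (int)eps.size();
  // threshold index per block entry: first eps index with d <= eps
  uint32_t add[64];
  for (int e = 0; e < E; ++e) add[e] = 0u;
  int bit = 0;
  for (int a = 0; a < N; ++a) {
    for (int b = 0; b < N; ++b, ++bit) {
      double d = std::fabs(x[i + a] - x[j + b]);
      // branchless count of grid values below d == lower_bound index
      int t = 0;
      for (int e = 0; e < E; ++e) t += (d > eps[e]);
      if (t < E) add[t] |= (1u << bit);
    }
  }
  uint32_t code = 0;
  for (int e = 0; e < E; ++e) {
    code |= add[e];
    uint32_t *cell = &dc.tab[(size_t)e * dc.n_codes + code];
    if (*cell == 0) dc.touched[e].push_back(code);
    ++(*cell);
  }
}

static std::vector<double> entropies_from_counts(const DenseCounts &dc,
                                                 double total) {
  std::vector<double> S(dc.n_eps);
  const double lt = std::log(total);
  for (int e = 0; e < dc.n_eps; ++e) {
    double acc = 0.0;
    for (uint32_t c : dc.touched[e]) {
      double cnt = (double)dc.tab[(size_t)e * dc.n_codes + c];
      acc += cnt * std::log(cnt);
    }
    S[e] = lt - acc / total;
  }
  return S;
}

static void check_N(int N) {
  if (N < 1 || N > 4)
    stop("microstate size N must be between 1 and 4 (dense code table)");
}

// Entropy over an eps grid for one segment; K sampled anchor pairs.
// Returns S (nats) per eps in the given ascending grid.
// [[Rcpp::export]]
NumericVector cpp_entropy_over_grid(NumericVector x, int N, int K,
                                    NumericVector eps_grid, double seed) {
  const int L = x.size();
  check_N(N);
  if (L < N) stop("segment shorter than microstate size N");
  if (K < 1) stop("K must be >= 1");
  const int M = L - N + 1;
  uint64_t rng = (uint64_t)seed + 0x51ed2701ULL;
  std::vector<double> eps(eps_grid.begin(), eps_grid.end());
  if (!std::is_sorted(eps.begin(), eps.end())) stop("eps grid must be ascending");
  DenseCounts dc((int)eps.size(), 1 << (N * N));
  const double *xp = REAL(x);
  for (int k = 0; k < K; ++k) {
    int i = rand_below(rng, M);
    int j = rand_below(rng, M);
    count_anchor_dense(xp, i, j, N, eps, dc);
  }
  std::vector<double> S = entropies_from_counts(dc, (double)K);
  return wrap(S);
}

// Microstate frequency distribution at a single eps. exhaustive = all
// (L-N+1)^2 anchor pairs; otherwise K sampled pairs.
// [[Rcpp::export]]
List cpp_microstate_counts(NumericVector x, double eps, int N, int K,
                           double seed, bool exhaustive) {
  const int L = x.size();
  check_N(N);
  if (L < N) stop("segment shorter than microstate size N");
  const int M = L - N + 1;
  std::unordered_map<uint32_t, double> counts;
  const double *xp = REAL(x);
  double total;
  auto code_at = [&](int i, int j) {
    uint32_t code = 0;
    int bit = 0;
    for (int a = 0; a < N; ++a)
      for (int b = 0; b < N; ++b, ++bit)
        if (std::fabs(xp[i + a] - xp[j + b]) <= eps) code |= (1u << bit);
    return code;
  };
  if (exhaustive) {
    total = (double)M * (double)M;
    for (int i = 0; i < M; ++i)
      for (int j = 0; j < M; ++j) counts[code_at(i, j)] += 1.0;
  } else {
    if (K < 1) stop("K must be >= 1");
    total = (double)K;
    uint64_t rng = (uint64_t)seed + 0x51ed2701ULL;
    for (int k = 0; k < K; ++k)
      counts[code_at(rand_below(rng, M), rand_below(rng, M))] += 1.0;
  }
  std::vector<double> codes, freq;
  codes.reserve(counts.size());
  freq.reserve(counts.size());
  for (auto &kv : counts) {
    codes.push_back((double)kv.first);
    freq.push_back(kv.second / total);
  }
  return List::create(_["code"] = codes, _["prob"] = freq);
}

// Per-segment maximum-entropy computation for a whole channel signal.
// The signal is cut into n_pieces equal segments (floor rule); each segment
// gets its own eps grid (distance quantiles) and its own RNG stream seeded
// from seeds[segment].
// [[Rcpp::export]]
List cpp_channel_entropy(NumericVector x, int n_pieces, int N, int K,
                         int n_eps, double q_lo, double q_hi, int n_dist_pairs,
                         NumericVector seeds) {
  const int L = x.size();
  check_N(N);
  if (n_pieces < 1) stop("n_pieces must be >= 1");
  if (L < n_pieces) stop("signal shorter than n_pieces");
  const int seg_len = L / n_pieces;
  if (seg_len < N) stop("segments shorter than microstate size N");
  if (seeds.size() != n_pieces) stop("need one seed per segment");
  NumericVector S_max(n_pieces), eps_star(n_pieces);
  DenseCounts dc(n_eps, 1 << (N * N));
  const int M = seg_len - N + 1;
  for (int s = 0; s < n_pieces; ++s) {
    const double *xs = REAL(x) + (size_t)s * seg_len;
    uint64_t rng = (uint64_t)seeds[s] + 0x51ed2701ULL;
    std::vector<double> eps =
        eps_grid_from_distances(xs, seg_len, n_eps, q_lo, q_hi, n_dist_pairs, rng);
    if (eps.back() <= 0.0) {  // (near-)constant segment
      S_max[s] = 0.0;
      eps_star[s] = 0.0;
      continue;
    }
    dc.reset();
    for (int k = 0; k < K; ++k) {
      int i = rand_below(rng, M);
      int j = rand_below(rng, M);
      count_anchor_dense(xs, i, j, N, eps, dc);
    }
    std::vector<double> S = entropies_from_counts(dc, (double)K);
    int best = 0;
    for (int e = 1; e < n_eps; ++e)
      if (S[e] > S[best]) best = e;  // strict: ties keep the smaller eps
    S_max[s] = S[best];
    eps_star[s] = eps[best];
  }
  return List::create(_["S_max"] = S_max, _["eps_star"] = eps_star,
                      _["seg_len"] = seg_len);
}

// Single-segment maximum entropy with a quantile-based eps grid. Uses one
// RNG stream for the grid subsample then the anchors, mirroring
// cpp_channel_entropy so the two paths agree exactly for a shared seed.
// [[Rcpp::export]]
List cpp_segment_max_entropy(NumericVector x, int N, int K, int n_eps,
                             double q_lo, double q_hi, int n_dist_pairs,
                             double seed) {
  const int L = x.size();
  check_N(N);
  if (L < N) stop("segment shorter than microstate size N");
  if (K < 1) stop("K must be >= 1");
  uint64_t rng = (uint64_t)seed + 0x51ed2701ULL;
  std::vector<double> eps =
      eps_grid_from_distances(REAL(x), L, n_eps, q_lo, q_hi, n_dist_pairs, rng);
  if (eps.back() <= 0.0) {
    return List::create(_["S_max"] = 0.0, _["eps_star"] = 0.0,
                        _["S"] = NumericVector(n_eps, 0.0),
                        _["eps_grid"] = wrap(eps), _["constant"] = true);
  }
  DenseCounts dc(n_eps, 1 << (N * N));
  const int M = L - N + 1;
  const double *xp = REAL(x);
  for (int k = 0; k < K; ++k) {
    int i = rand_below(rng, M);
    int j = rand_below(rng, M);
    count_anchor_dense(xp, i, j, N, eps, dc);
  }
  std::vector<double> S = entropies_from_counts(dc, (double)K);
  int best = 0;
  for (int e = 1; e < n_eps; ++e)
    if (S[e] > S[best]) best = e;
  return List::create(_["S_max"] = S[best], _["eps_star"] = eps[best],
                      _["S"] = wrap(S), _["eps_grid"] = wrap(eps),
                      _["constant"] = false);
}

// Distance-quantile eps grid, exposed so the R-level single-segment path
// uses the identical realized grid as the channel kernel.
// [[Rcpp::export]]
NumericVector cpp_eps_grid(NumericVector x, int n_eps, double q_lo,
                           double q_hi, int n_dist_pairs, double seed) {
  uint64_t rng = (uint64_t)seed + 0x51ed2701ULL;
  std::vector<double> g = eps_grid_from_distances(REAL(x), x.size(), n_eps,
                                                  q_lo, q_hi, n_dist_pairs, rng);
  return wrap(g);
}
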