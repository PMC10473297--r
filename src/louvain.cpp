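#include <Rcpp.h>
#include <random>
#include <vector>
#include <numeric>
#include <algorithm>

using namespace Rcpp;

// Signed-modularity Louvain on a dense symmetric "modularity matrix" B with
// zero diagonal (aggregated levels carry within-community weight as
// self-loops, which never enter move gains).  The objective is
// Q = sum_{i != j, g(i)==g(j)} B_ij; a node move's gain is twice the
// difference between its summed weight to the destination and to the rest of
// its current community, so raw sums are compared directly.  Like the
// iterated generalized-Louvain schemes used for signed matrices, the
// algorithm alternates node-level sweeps with multilevel coarsening until
// the objective stops improving; with signed weights a node may also split
// off into an empty community when its net attachment is negative.

static const double EPS = 1e-12;

static int relabel_consecutive(std::vector<int>& lab) {
  std::vector<int> map(lab.size(), -1);
  int k = 0;
  for (size_t i = 0; i < lab.size(); ++i) {
    if (map[lab[i]] < 0) map[lab[i]] = k++;
    lab[i] = map[lab[i]];
  }
  return k;
}

// greedy local moves (random order sweeps until quiescent); returns whether
// any move was made
static bool local_moves(const std::vector<double>& W, int m,
                        std::vector<int>& lab, std::mt19937& rng) {
  std::vector<int> order(m), csize(m, 0);
  std::iota(order.begin(), order.end(), 0);
  for (int i = 0; i < m; ++i) ++csize[lab[i]];
  std::vector<double> cw(m);
  bool any = false, moving = true;
  while (moving) {
    moving = false;
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < m; ++oi) {
      int i = order[oi];
      std::fill(cw.begin(), cw.end(), 0.0);
      const double* col = &W[(size_t)i * m];
      for (int j = 0; j < m; ++j)
        if (j != i) cw[lab[j]] += col[j];
      int cur = lab[i], best = cur;
      double bestw = cw[cur];
      for (int j = 0; j < m; ++j) {
        int c = lab[j];
        if (cw[c] > bestw + EPS) { bestw = cw[c]; best = c; }
      }
      if (bestw < -EPS && csize[cur] > 1) {
        for (int c = 0; c < m; ++c)
          if (csize[c] == 0) { best = c; bestw = 0.0; break; }
      }
      if (best != cur) {
        lab[i] = best; --csize[cur]; ++csize[best];
        any = moving = true;
      }
    }
  }
  return any;
}

static std::vector<double> aggregate(const std::vector<double>& W, int m,
                                     const std::vector<int>& lab, int k) {
  std::vector<double> A((size_t)k * k, 0.0);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < m; ++i)
      A[(size_t)lab[i] + (size_t)k * lab[j]] += W[(size_t)i + (size_t)m * j];
  return A;
}

static double partition_q(const std::vector<double>& B, int n,
                          const std::vector<int>& lab) {
  double q = 0.0;
  for (int j = 0; j < n; ++j) {
    const double* col = &B[(size_t)j * n];
    for (int i = 0; i < n; ++i)
      if (i != j && lab[i] == lab[j]) q += col[i];
  }
  return q;
}

static void louvain_once(const std::vector<double>& B, int n,
                         std::mt19937& rng, std::vector<int>& lab) {
  lab.assign(n, 0);
  std::iota(lab.begin(), lab.end(), 0);
  double q_cur = 0.0; // singleton partition has Q = 0 (zero diagonal)
  for (;;) {
    // node-level sweep from the current partition
    local_moves(B, n, lab, rng);
    q_cur = partition_q(B, n, lab);
    // multilevel coarsening on top of the current partition
    std::vector<int> node2super(lab);
    int k = relabel_consecutive(node2super);
    std::vector<double> W = aggregate(B, n, node2super, k);
    bool coarsened = false;
    for (;;) {
      std::vector<int> slab(k);
      std::iota(slab.begin(), slab.end(), 0);
      if (!local_moves(W, k, slab, rng)) break;
      int k2 = relabel_consecutive(slab);
      for (int v = 0; v < n; ++v) node2super[v] = slab[node2super[v]];
      coarsened = true;
      if (k2 == k) break;
      W = aggregate(W, k, slab, k2);
      k = k2;
    }
    if (!coarsened) break;
    double q_new = partition_q(B, n, node2super);
    if (q_new > q_cur + EPS) {
      lab = node2super;
      q_cur = q_new;
    } else break;
  }
  relabel_consecutive(lab);
}

// [[Rcpp::export]]
IntegerVector cpp_louvain(NumericMatrix B, int seed) {
  int n = B.nrow();
  std::vector<double> W(B.begin(), B.end());
  std::mt19937 rng((unsigned)seed);
  std::vector<int> lab(n);
  louvain_once(W, n, rng, lab);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = lab[i] + 1;
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_louvain_ensemble(NumericMatrix B, int n_runs, int seed) {
  int n = B.nrow();
  std::vector<double> W(B.begin(), B.end());
  std::mt19937 rng((unsigned)seed);
  IntegerMatrix out(n, n_runs);
  std::vector<int> lab(n);
  for (int r = 0; r < n_runs; ++r) {
    louvain_once(W, n, rng, lab);
    for (int i = 0; i < n; ++i) out(i, r) = lab[i] + 1;
  }
  return out;
}

// Co-classification frequency across ensemble runs plus its permutation-null
// expectation: under random relabelling of a run's partition every off-
// diagonal pair is co-assigned with probability sum_c n_c (n_c - 1) / (P(P-1)).
// [[Rcpp::export]]
List cpp_coclassification(IntegerMatrix L) {
  int n = L.nrow(), R = L.ncol();
  NumericMatrix D(n, n);
  double d0 = 0.0;
  for (int r = 0; r < R; ++r) {
    int kmax = 0;
    for (int i = 0; i < n; ++i) kmax = std::max(kmax, L(i, r));
    std::vector<double> sz(kmax, 0.0);
    for (int i = 0; i < n; ++i) sz[L(i, r) - 1] += 1.0;
    double s = 0.0;
    for (int c = 0; c < kmax; ++c) s += sz[c] * (sz[c] - 1.0);
    d0 += s / ((double)n * (n - 1.0));
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        if (L(i, r) == L(j, r)) D(i, j) += 1.0;
  }
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) D(i, j) /= R;
  return List::create(_["D"] = D, _["d0"] = d0 / R);
}

// Null modularity contributions: random assignment of nodes to communities
// with fixed sizes; q_c summed over ordered pairs (diagonal of B is zero).
// Returns n_perm x K matrix of null q_c values.
// [[Rcpp::export]]
NumericMatrix cpp_perm_qc(NumericMatrix B, IntegerVector sizes,
                          int n_perm, int seed) {
  int n = B.nrow(), K = sizes.size();
  std::vector<int> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  std::mt19937 rng((unsigned)seed);
  NumericMatrix out(n_perm, K);
  for (int p = 0; p < n_perm; ++p) {
    std::shuffle(idx.begin(), idx.end(), rng);
    int pos = 0;
    for (int c = 0; c < K; ++c) {
      int s = sizes[c];
      double q = 0.0;
      for (int a = 0; a < s; ++a) {
        const double* col = &B[(size_t)idx[pos + a] * n];
        for (int b = 0; b < s; ++b) q += col[idx[pos + b]];
      }
      out(p, c) = q;
      pos += s;
    }
  }
  return out;
}
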