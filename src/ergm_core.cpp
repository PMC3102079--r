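// Core ERGM machinery: incremental change statistics over a bitset adjacency
// structure, the Metropolis dyad-toggle sampler, the MPLE design matrix, and
// exact enumeration of the sample space for small n (Gray-code order, so each
// successive graph differs by one dyad toggle and statistics update in O(deg)).
//
// Term kind codes (kept in sync with R/model.R):
//   1 edges, 2 two_path, 3 gwd, 4 gwesp, 5 gwnsp, 6 gwdsp, 7 nodematch

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <random>

using namespace Rcpp;

enum TermKind {
  T_EDGES = 1, T_TWOPATH = 2, T_GWD = 3, T_GWESP = 4,
  T_GWNSP = 5, T_GWDSP = 6, T_NODEMATCH = 7
};

struct Terms {
  std::vector<int> kind;
  std::vector<double> tau;
  std::vector<double> etau;                  // exp(tau) per term
  std::vector<std::vector<double> > rpow;    // (1 - exp(-tau))^s, s = 0..n
  IntegerMatrix attr;                        // n x p node attribute codes
  int p;
  bool needSP;                               // any shared-partner term present

  Terms(IntegerVector kinds, NumericVector taus, IntegerMatrix attrs, int n)
      : attr(attrs) {
    p = kinds.size();
    needSP = false;
    kind.resize(p); tau.resize(p); etau.resize(p); rpow.resize(p);
    for (int t = 0; t < p; ++t) {
      kind[t] = kinds[t];
      tau[t] = taus[t];
      etau[t] = std::exp(taus[t]);
      if (kind[t] == T_GWD || kind[t] == T_GWESP ||
          kind[t] == T_GWNSP || kind[t] == T_GWDSP) {
        double r = 1.0 - std::exp(-taus[t]);
        rpow[t].resize(n + 2);
        rpow[t][0] = 1.0;
        for (int s = 1; s <= n + 1; ++s) rpow[t][s] = rpow[t][s - 1] * r;
        if (kind[t] != T_GWD) needSP = true;
      }
    }
  }
};

struct Graph {
  int n, W;
  std::vector<uint64_t> adj;  // row-major bitsets, n rows of W words
  std::vector<int> deg;

  explicit Graph(int n_) : n(n_), W((n_ + 63) / 64),
                           adj((size_t)n_ * ((n_ + 63) / 64), 0), deg(n_, 0) {}

  inline bool has(int i, int j) const {
    return (adj[(size_t)i * W + (j >> 6)] >> (j & 63)) & 1ULL;
  }
  inline void toggle(int i, int j) {
    adj[(size_t)i * W + (j >> 6)] ^= (1ULL << (j & 63));
    adj[(size_t)j * W + (i >> 6)] ^= (1ULL << (i & 63));
    if (has(i, j)) { ++deg[i]; ++deg[j]; } else { --deg[i]; --deg[j]; }
  }
  // shared partners: common neighbours of i and j
  inline int sp(int i, int j) const {
    const uint64_t *ri = &adj[(size_t)i * W], *rj = &adj[(size_t)j * W];
    int c = 0;
    for (int w = 0; w < W; ++w) c += __builtin_popcountll(ri[w] & rj[w]);
    return c;
  }
  inline void neighbors(int i, std::vector<int> &out) const {
    out.clear();
    const uint64_t *ri = &adj[(size_t)i * W];
    for (int w = 0; w < W; ++w) {
      uint64_t word = ri[w];
      while (word) {
        out.push_back(w * 64 + __builtin_ctzll(word));
        word &= word - 1;
      }
    }
  }
};

// Change statistics for dyad (i, j): g(y + ij) - g(y - ij). The caller must
// ensure the edge (i, j) is ABSENT from g when this is called.
static void changeStats(const Graph &G, int i, int j, const Terms &T,
                        std::vector<int> &nbI, std::vector<int> &nbJ,
                        std::vector<int> &spI, std::vector<int> &spJ,
                        double *out) {
  int spij = 0;
  if (T.needSP) {
    spij = G.sp(i, j);
    G.neighbors(i, nbI);
    G.neighbors(j, nbJ);
    // spI[k]: shared partners of dyad (i, nbJ[k]); spJ[k]: of (j, nbI[k])
    spI.resize(nbJ.size());
    spJ.resize(nbI.size());
    for (size_t k = 0; k < nbJ.size(); ++k) spI[k] = G.sp(i, nbJ[k]);
    for (size_t k = 0; k < nbI.size(); ++k) spJ[k] = G.sp(j, nbI[k]);
  }
  for (int t = 0; t < T.p; ++t) {
    double d = 0.0;
    switch (T.kind[t]) {
    case T_EDGES:
      d = 1.0;
      break;
    case T_TWOPATH:
      // sum_v C(deg v, 2): degrees of i and j each rise by one
      d = G.deg[i] + G.deg[j];
      break;
    case T_GWD: {
      const std::vector<double> &rp = T.rpow[t];
      d = rp[G.deg[i]] + rp[G.deg[j]];
      break;
    }
    case T_GWESP: {
      const std::vector<double> &rp = T.rpow[t];
      d = T.etau[t] * (1.0 - rp[spij]);
      for (size_t k = 0; k < nbJ.size(); ++k)
        if (G.has(i, nbJ[k])) d += rp[spI[k]];
      for (size_t k = 0; k < nbI.size(); ++k)
        if (G.has(j, nbI[k])) d += rp[spJ[k]];
      break;
    }
    case T_GWNSP: {
      const std::vector<double> &rp = T.rpow[t];
      d = -T.etau[t] * (1.0 - rp[spij]);
      for (size_t k = 0; k < nbJ.size(); ++k)
        if (!G.has(i, nbJ[k]) && nbJ[k] != i) d += rp[spI[k]];
      for (size_t k = 0; k < nbI.size(); ++k)
        if (!G.has(j, nbI[k]) && nbI[k] != j) d += rp[spJ[k]];
      break;
    }
    case T_GWDSP: {
      const std::vector<double> &rp = T.rpow[t];
      for (size_t k = 0; k < nbJ.size(); ++k)
        if (nbJ[k] != i) d += rp[spI[k]];
      for (size_t k = 0; k < nbI.size(); ++k)
        if (nbI[k] != j) d += rp[spJ[k]];
      break;
    }
    case T_NODEMATCH:
      d = (T.attr(i, t) == T.attr(j, t)) ? 1.0 : 0.0;
      break;
    default:
      stop("unknown term kind code");
    }
    out[t] = d;
  }
}

static Graph buildGraph(int n, const IntegerMatrix &edges) {
  Graph G(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    if (i == j) stop("self-loop in edge list");
    if (!G.has(i, j)) G.toggle(i, j);
  }
  return G;
}

// Statistic vector by incremental build-up from the empty graph (all
// statistics used here are zero on the empty graph).
static void statVector(Graph &G, const IntegerMatrix &edges, const Terms &T,
                       double *g) {
  std::vector<int> nbI, nbJ, spI, spJ;
  std::vector<double> d(T.p);
  for (int t = 0; t < T.p; ++t) g[t] = 0.0;
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    changeStats(G, i, j, T, nbI, nbJ, spI, spJ, d.data());
    for (int t = 0; t < T.p; ++t) g[t] += d[t];
    G.toggle(i, j);
  }
}

// [[Rcpp::export]]
NumericVector cpp_statistic_vector(int n, IntegerMatrix edges,
                                   IntegerVector kinds, NumericVector taus,
                                   IntegerMatrix attrs) {
  Terms T(kinds, taus, attrs, n);
  Graph G(n);
  NumericVector g(T.p);
  statVector(G, edges, T, REAL(g));
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_change_stats(int n, IntegerMatrix edges, int i, int j,
                               IntegerVector kinds, NumericVector taus,
                               IntegerMatrix attrs) {
  Terms T(kinds, taus, attrs, n);
  Graph G = buildGraph(n, edges);
  int i0 = i - 1, j0 = j - 1;
  if (i0 == j0) stop("self-loop dyad");
  bool present = G.has(i0, j0);
  if (present) G.toggle(i0, j0);
  std::vector<int> nbI, nbJ, spI, spJ;
  NumericVector out(T.p);
  changeStats(G, i0, j0, T, nbI, nbJ, spI, spJ, REAL(out));
  if (present) G.toggle(i0, j0);
  return out;
}

// Design matrix of change statistics over all C(n,2) dyads, plus the edge
// indicator response (the MPLE logistic regression inputs).
// [[Rcpp::export]]
List cpp_change_stat_matrix(int n, IntegerMatrix edges, IntegerVector kinds,
                            NumericVector taus, IntegerMatrix attrs) {
  Terms T(kinds, taus, attrs, n);
  Graph G = buildGraph(n, edges);
  int M = n * (n - 1) / 2;
  NumericMatrix X(M, T.p);
  IntegerVector y(M);
  IntegerMatrix dyads(M, 2);
  std::vector<int> nbI, nbJ, spI, spJ;
  std::vector<double> d(T.p);
  int row = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j, ++row) {
      bool present = G.has(i, j);
      if (present) G.toggle(i, j);
      changeStats(G, i, j, T, nbI, nbJ, spI, spJ, d.data());
      if (present) G.toggle(i, j);
      for (int t = 0; t < T.p; ++t) X(row, t) = d[t];
      y[row] = present ? 1 : 0;
      dyads(row, 0) = i + 1;
      dyads(row, 1) = j + 1;
    }
  }
  return List::create(_["X"] = X, _["y"] = y, _["dyads"] = dyads);
}

static IntegerMatrix extractEdges(const Graph &G) {
  int m = 0;
  for (int i = 0; i < G.n; ++i) m += G.deg[i];
  m /= 2;
  IntegerMatrix E(m, 2);
  int row = 0;
  for (int i = 0; i < G.n - 1; ++i)
    for (int j = i + 1; j < G.n; ++j)
      if (G.has(i, j)) { E(row, 0) = i + 1; E(row, 1) = j + 1; ++row; }
  return E;
}

// Metropolis sampler over dyad toggles. Proposal: uniform random dyad;
// acceptance min(1, exp(+-theta'delta)). Returns retained draws' sufficient
// statistics, edge counts, and (optionally) edge lists.
// [[Rcpp::export]]
List cpp_sample(int n, IntegerVector kinds, NumericVector taus,
                IntegerMatrix attrs, NumericVector theta,
                IntegerMatrix init_edges, double burnin, double thin,
                int count, int seed, bool return_edges) {
  Terms T(kinds, taus, attrs, n);
  Graph G(n);
  std::vector<double> g(T.p);
  statVector(G, init_edges, T, g.data());

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> nbI, nbJ, spI, spJ;
  std::vector<double> d(T.p);
  long long accepted = 0, proposed = 0;

  NumericMatrix stats(count, T.p);
  IntegerVector ecount(count);
  List draws(return_edges ? count : 0);

  long long burn = (long long)burnin;
  long long th = (long long)(thin < 0 ? 0 : thin);

  auto sweep = [&](long long steps) {
    for (long long s = 0; s < steps; ++s) {
      int i = pick(rng), j = pick(rng);
      if (i == j) continue;  // counts as a (rejected) proposal on a loop-free space
      if (i > j) std::swap(i, j);
      ++proposed;
      bool present = G.has(i, j);
      if (present) G.toggle(i, j);
      changeStats(G, i, j, T, nbI, nbJ, spI, spJ, d.data());
      double lr = 0.0;
      for (int t = 0; t < T.p; ++t) lr += theta[t] * d[t];
      if (present) lr = -lr;  // proposal removes the edge
      bool accept = (lr >= 0.0) || (unif(rng) < std::exp(lr));
      if (accept) {
        ++accepted;
        if (!present) {          // edge added
          G.toggle(i, j);
          for (int t = 0; t < T.p; ++t) g[t] += d[t];
        } else {                 // edge stays removed
          for (int t = 0; t < T.p; ++t) g[t] -= d[t];
        }
      } else {
        if (present) G.toggle(i, j);  // restore
      }
    }
  };

  sweep(burn);
  for (int k = 0; k < count; ++k) {
    sweep(th);
    for (int t = 0; t < T.p; ++t) stats(k, t) = g[t];
    int m = 0;
    for (int i = 0; i < n; ++i) m += G.deg[i];
    ecount[k] = m / 2;
    if (return_edges) draws[k] = extractEdges(G);
  }

  return List::create(_["stats"] = stats, _["n_edges"] = ecount,
                      _["edges"] = draws,
                      _["acceptance_rate"] =
                          proposed > 0 ? (double)accepted / proposed : 0.0);
}

// Exact enumeration of all 2^C(n,2) labeled graphs in Gray-code order.
// Returns log kappa(theta), E_theta[g] and Cov_theta[g].
// [[Rcpp::export]]
List cpp_exact(int n, IntegerVector kinds, NumericVector taus,
               IntegerMatrix attrs, NumericVector theta) {
  Terms T(kinds, taus, attrs, n);
  int M = n * (n - 1) / 2;
  if (M > 25) stop("enumeration limit exceeded");
  std::vector<std::pair<int, int> > dyads;
  dyads.reserve(M);
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) dyads.push_back(std::make_pair(i, j));

  std::vector<int> nbI, nbJ, spI, spJ;
  std::vector<double> d(T.p);
  uint64_t nstates = 1ULL << M;

  // pass closure: enumerate, calling f(value, g) at every state
  auto enumerate = [&](const std::function<void(double, const double *)> &f) {
    Graph G(n);
    std::vector<double> g(T.p, 0.0);
    double val = 0.0;
    f(val, g.data());
    for (uint64_t s = 1; s < nstates; ++s) {
      int b = __builtin_ctzll(s);
      int i = dyads[b].first, j = dyads[b].second;
      bool present = G.has(i, j);
      if (present) G.toggle(i, j);
      changeStats(G, i, j, T, nbI, nbJ, spI, spJ, d.data());
      if (!present) G.toggle(i, j);
      double sign = present ? -1.0 : 1.0;
      val = 0.0;
      for (int t = 0; t < T.p; ++t) {
        g[t] += sign * d[t];
        val += theta[t] * g[t];
      }
      if (!present) { /* edge now added above */ } else { /* removed */ }
      f(val, g.data());
    }
  };

  double smax = -INFINITY;
  enumerate([&](double v, const double *) { if (v > smax) smax = v; });

  int p = T.p;
  double Z = 0.0;
  std::vector<double> m1(p, 0.0);
  std::vector<double> m2((size_t)p * p, 0.0);
  enumerate([&](double v, const double *g) {
    double w = std::exp(v - smax);
    Z += w;
    for (int a = 0; a < p; ++a) {
      m1[a] += w * g[a];
      for (int b = 0; b <= a; ++b) m2[(size_t)a * p + b] += w * g[a] * g[b];
    }
  });

  NumericVector mean(p);
  NumericMatrix cov(p, p);
  for (int a = 0; a < p; ++a) mean[a] = m1[a] / Z;
  for (int a = 0; a < p; ++a)
    for (int b = 0; b <= a; ++b) {
      double c = m2[(size_t)a * p + b] / Z - mean[a] * mean[b];
      cov(a, b) = c;
      cov(b, a) = c;
    }
  return List::create(_["log_kappa"] = smax + std::log(Z), _["mean"] = mean,
                      _["cov"] = cov);
}
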