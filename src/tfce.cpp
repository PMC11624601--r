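#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- union-find -----------------------------------------------------------

static inline int uf_find(std::vector<int>& parent, int x) {
  int r = x;
  while (parent[r] != r) r = parent[r];
  while (parent[x] != r) { int nx = parent[x]; parent[x] = r; x = nx; }
  return r;
}

static inline void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[rb] = ra;
}

// ---- TFCE enhancement of a single-signed map ------------------------------
//
// m: length V*T map (point p = v + V*t); only values >= threshold count.
// Spatiotemporal adjacency: spatial edges at equal t, plus (v,t)-(v,t+1).
// Integration: left-Riemann steps of size dh at h = h0+dh, h0+2dh, ... <= hmax,
// plus a final partial step of width (hmax - h_last) at height hmax.
//
// Implementation: thresholds are processed in descending order with an
// incremental union-find; per-component contributions e(h)^E h^H dh are
// accumulated on the component roots and distributed to members through
// offset-carrying path compression, so the whole map costs
// O(P + edges + n_thresh * n_components) instead of a full sweep per
// threshold.
struct TfceAcc {
  std::vector<int> parent, size;
  std::vector<double> offset, pending;
  explicit TfceAcc(int P) : parent(P), size(P, 0), offset(P, 0.0),
                            pending(P, 0.0) {}
  // root of p; compresses the path and folds offsets so that offset[x] is
  // always the value owed to x relative to its (new) parent
  int find(int p, std::vector<int>& stack_buf) {
    int r = p;
    while (parent[r] != r) { stack_buf.push_back(r); r = parent[r]; }
    double off = 0.0;
    for (int i = (int)stack_buf.size() - 1; i >= 0; --i) {
      const int x = stack_buf[i];
      off += offset[x];
      parent[x] = r;
      offset[x] = off;
    }
    stack_buf.clear();
    return r;
  }
  // attach root rb under root ra
  void link(int ra, int rb) {
    parent[rb] = ra;
    offset[rb] = pending[rb] - pending[ra];
    size[ra] += size[rb];
  }
};

static void tfce_one_sign(const double* m, int V, int T,
                          const IntegerMatrix& edges,
                          double E, double H, double h0, double dh,
                          double* out) {
  const int P = V * T;
  double hmax = 0.0;
  for (int p = 0; p < P; ++p) if (m[p] > hmax) hmax = m[p];
  if (hmax <= h0) return;
  if ((hmax - h0) / dh > 2e5)
    Rcpp::stop("statistic map maximum too large relative to the TFCE step dh");
  const int K = (int)std::floor((hmax - h0) / dh + 1e-9);
  const double h_top = h0 + K * dh;

  // bucket points by the highest full threshold they survive
  std::vector<int> bin(P, -1);
  std::vector<int> bucket_start(K + 2, 0);
  for (int p = 0; p < P; ++p) {
    if (m[p] <= h0) continue;
    int k = (int)std::floor((m[p] - h0) / dh + 1e-9);
    if (k > K) k = K;
    bin[p] = k;
    ++bucket_start[k + 1];
  }
  // prefix sums -> CSR-style buckets (bucket k occupies
  // [bucket_start[k], bucket_start[k+1]) of order[])
  for (int k = 1; k <= K + 1; ++k) bucket_start[k] += bucket_start[k - 1];
  std::vector<int> order(bucket_start[K + 1]);
  {
    std::vector<int> cursor(bucket_start.begin(), bucket_start.end() - 1);
    for (int p = 0; p < P; ++p)
      if (bin[p] >= 0) order[cursor[bin[p]]++] = p;
  }

  // spatial adjacency lists (built per call; edges are per-hemisphere small)
  std::vector<int> deg(V, 0);
  const int nE = edges.nrow();
  for (int e = 0; e < nE; ++e) { ++deg[edges(e, 0)]; ++deg[edges(e, 1)]; }
  std::vector<int> adj_start(V + 1, 0);
  for (int v = 0; v < V; ++v) adj_start[v + 1] = adj_start[v] + deg[v];
  std::vector<int> adj(adj_start[V]);
  {
    std::vector<int> cur(adj_start.begin(), adj_start.end() - 1);
    for (int e = 0; e < nE; ++e) {
      const int a = edges(e, 0), b = edges(e, 1);
      adj[cur[a]++] = b;
      adj[cur[b]++] = a;
    }
  }

  TfceAcc uf(P);
  std::vector<char> active(P, 0);
  std::vector<int> roots;            // superset of current roots; lazily pruned
  std::vector<int> stack_buf;
  roots.reserve(256);

  auto activate = [&](int p) {
    active[p] = 1;
    uf.parent[p] = p; uf.size[p] = 1; uf.offset[p] = 0.0; uf.pending[p] = 0.0;
    roots.push_back(p);
    const int v = p % V, t = p / V;
    for (int j = adj_start[v]; j < adj_start[v + 1]; ++j) {
      const int q = adj[j] + V * t;
      if (active[q]) {
        int ra = uf.find(p, stack_buf), rb = uf.find(q, stack_buf);
        if (ra != rb) uf.link(uf.size[ra] >= uf.size[rb] ? ra : rb,
                              uf.size[ra] >= uf.size[rb] ? rb : ra);
      }
    }
    if (t > 0 && active[p - V]) {
      int ra = uf.find(p, stack_buf), rb = uf.find(p - V, stack_buf);
      if (ra != rb) uf.link(uf.size[ra] >= uf.size[rb] ? ra : rb,
                            uf.size[ra] >= uf.size[rb] ? rb : ra);
    }
    if (t + 1 < T && active[p + V]) {
      int ra = uf.find(p, stack_buf), rb = uf.find(p + V, stack_buf);
      if (ra != rb) uf.link(uf.size[ra] >= uf.size[rb] ? ra : rb,
                            uf.size[ra] >= uf.size[rb] ? rb : ra);
    }
  };

  auto contribute = [&](double h, double weight) {
    const double hh = weight * std::pow(h, H);
    size_t w = 0;
    for (size_t i = 0; i < roots.size(); ++i) {
      const int r = roots[i];
      if (uf.parent[r] != r) continue;         // merged away; prune
      uf.pending[r] += hh * std::pow((double)uf.size[r], E);
      roots[w++] = r;
    }
    roots.resize(w);
  };

  // final partial step at the map maximum (points with m >= hmax)
  if (hmax > h_top + 1e-9 * dh) {
    for (int p = 0; p < P; ++p)
      if (m[p] >= hmax - 1e-9 * dh && !active[p]) activate(p);
    contribute(hmax, hmax - h_top);
  }
  for (int k = K; k >= 1; --k) {
    for (int i = bucket_start[k]; i < bucket_start[k + 1]; ++i)
      if (!active[order[i]]) activate(order[i]);
    contribute(h0 + k * dh, dh);
  }

  for (int p = 0; p < P; ++p) {
    if (!active[p]) continue;
    const int r = uf.find(p, stack_buf);
    out[p] += uf.pending[r] + (p == r ? 0.0 : uf.offset[p]);
  }
}

static void tfce_map(const double* stat, int V, int T,
                     const IntegerMatrix& edges,
                     double E, double H, double h0, double dh,
                     bool two_sided, double* out) {
  const int P = V * T;
  std::fill(out, out + P, 0.0);
  tfce_one_sign(stat, V, T, edges, E, H, h0, dh, out);
  if (two_sided) {
    std::vector<double> neg(P), nout(P, 0.0);
    for (int p = 0; p < P; ++p) neg[p] = -stat[p];
    tfce_one_sign(neg.data(), V, T, edges, E, H, h0, dh, nout.data());
    for (int p = 0; p < P; ++p) out[p] -= nout[p];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_tfce(NumericMatrix stat, IntegerMatrix edges,
                       double E, double H, double h0, double dh,
                       bool two_sided) {
  const int V = stat.nrow(), T = stat.ncol();
  NumericMatrix out(V, T);
  tfce_map(stat.begin(), V, T, edges, E, H, h0, dh, two_sided, out.begin());
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_connected_components(LogicalMatrix mask, IntegerMatrix edges) {
  const int V = mask.nrow(), T = mask.ncol(), P = V * T;
  std::vector<int> parent(P);
  for (int p = 0; p < P; ++p) parent[p] = p;
  const int nE = edges.nrow();
  for (int t = 0; t < T; ++t) {
    const int off = V * t;
    for (int e = 0; e < nE; ++e) {
      const int a = off + edges(e, 0), b = off + edges(e, 1);
      if (mask[a] && mask[b]) uf_union(parent, a, b);
    }
    if (t + 1 < T) for (int v = 0; v < V; ++v) {
      const int a = off + v, b = a + V;
      if (mask[a] && mask[b]) uf_union(parent, a, b);
    }
  }
  IntegerMatrix labels(V, T);
  std::vector<int> lab(P, 0);
  int next = 0;
  for (int p = 0; p < P; ++p) {
    if (!mask[p]) { labels[p] = 0; continue; }
    int r = uf_find(parent, p);
    if (lab[r] == 0) lab[r] = ++next;
    labels[p] = lab[r];
  }
  return labels;
}

// ---- t statistics ----------------------------------------------------------

// one-sample t across rows of X (n x P) with per-subject signs
static void t_one_sample(const NumericMatrix& X, const int* sign,
                         std::vector<double>& t) {
  const int n = X.nrow(), P = X.ncol();
  for (int p = 0; p < P; ++p) {
    double s = 0, ss = 0;
    const double* col = &X(0, p);
    for (int i = 0; i < n; ++i) {
      const double x = sign[i] * col[i];
      s += x; ss += x * x;
    }
    const double mean = s / n;
    double var = (ss - n * mean * mean) / (n - 1);
    if (var <= 0) {                    // degenerate: constant across subjects
      t[p] = (mean == 0.0) ? 0.0 : (mean > 0 ? 100.0 : -100.0);
      continue;
    }
    t[p] = mean / std::sqrt(var / n);
  }
}

// two-sample pooled-variance t across rows of X (n x P); grp[i] in {0,1},
// statistic = mean(group0) - mean(group1)
static void t_two_sample(const NumericMatrix& X, const int* grp,
                         std::vector<double>& t) {
  const int n = X.nrow(), P = X.ncol();
  int n0 = 0;
  for (int i = 0; i < n; ++i) if (grp[i] == 0) ++n0;
  const int n1 = n - n0;
  for (int p = 0; p < P; ++p) {
    double s0 = 0, ss0 = 0, s1 = 0, ss1 = 0;
    const double* col = &X(0, p);
    for (int i = 0; i < n; ++i) {
      if (grp[i] == 0) { s0 += col[i]; ss0 += col[i] * col[i]; }
      else             { s1 += col[i]; ss1 += col[i] * col[i]; }
    }
    const double m0 = s0 / n0, m1 = s1 / n1;
    const double sp = ((ss0 - n0 * m0 * m0) + (ss1 - n1 * m1 * m1)) / (n0 + n1 - 2);
    if (sp <= 0) {
      t[p] = (m0 == m1) ? 0.0 : (m0 > m1 ? 100.0 : -100.0);
      continue;
    }
    t[p] = (m0 - m1) / std::sqrt(sp * (1.0 / n0 + 1.0 / n1));
  }
}

// ---- permutation drivers ---------------------------------------------------
//
// X: n x (V*T) data (one-sample: per-subject difference maps; two-sample:
// per-subject differential maps). perms: n x n_perm matrix of signs (+1/-1)
// or group labels (0/1). Returns the observed TFCE map, the max |TFCE| per
// permutation, and per-point counts of permutations with |TFCE| >= observed.

static List perm_driver(const NumericMatrix& X, const IntegerVector& obs,
                        const IntegerMatrix& perms, int V, int T,
                        const IntegerMatrix& edges,
                        double E, double H, double h0, double dh,
                        bool two_sided, bool one_sample) {
  const int P = V * T, n_perm = perms.ncol();
  std::vector<double> t(P), enh(P);
  NumericMatrix tfce_obs(V, T), stat_obs(V, T);
  if (one_sample) t_one_sample(X, &obs[0], t); else t_two_sample(X, &obs[0], t);
  std::copy(t.begin(), t.end(), stat_obs.begin());
  tfce_map(t.data(), V, T, edges, E, H, h0, dh, two_sided, tfce_obs.begin());

  NumericVector max_null(n_perm);
  IntegerVector exceed(P);
  std::vector<int> pi(X.nrow());
  for (int k = 0; k < n_perm; ++k) {
    for (int i = 0; i < X.nrow(); ++i) pi[i] = perms(i, k);
    if (one_sample) t_one_sample(X, pi.data(), t);
    else            t_two_sample(X, pi.data(), t);
    tfce_map(t.data(), V, T, edges, E, H, h0, dh, two_sided, enh.data());
    double mx = 0.0;
    for (int p = 0; p < P; ++p) {
      const double a = std::fabs(enh[p]);
      if (a > mx) mx = a;
      if (a >= std::fabs(tfce_obs[p]) - 1e-12) ++exceed[p];
    }
    max_null[k] = mx;
  }
  return List::create(_["stat"] = stat_obs, _["tfce"] = tfce_obs,
                      _["max_null"] = max_null, _["exceed"] = exceed);
}

// [[Rcpp::export]]
List cpp_perm_one_sample(NumericMatrix X, IntegerMatrix signs, int V, int T,
                         IntegerMatrix edges, double E, double H,
                         double h0, double dh, bool two_sided) {
  IntegerVector obs(X.nrow(), 1);
  return perm_driver(X, obs, signs, V, T, edges, E, H, h0, dh, two_sided, true);
}

// [[Rcpp::export]]
List cpp_perm_two_sample(NumericMatrix X, IntegerVector grp,
                         IntegerMatrix perms, int V, int T,
                         IntegerMatrix edges, double E, double H,
                         double h0, double dh, bool two_sided) {
  return perm_driver(X, grp, perms, V, T, edges, E, H, h0, dh, two_sided, false);
}

// ---- zero-phase IIR filtering ---------------------------------------------

static void iir_forward(std::vector<double>& x, const NumericVector& b,
                        const NumericVector& a) {
  const int n = x.size(), nb = b.size(), na = a.size();
  std::vector<double> y(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < nb && j <= i; ++j) acc += b[j] * x[i - j];
    for (int j = 1; j < na && j <= i; ++j) acc -= a[j] * y[i - j];
    y[i] = acc / a[0];
  }
  x.swap(y);
}

// forward-backward filtering with odd-reflection padding, column-wise
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt(NumericMatrix x, NumericVector b, NumericVector a,
                           int npad) {
  const int n = x.nrow(), m = x.ncol();
  if (npad > n - 1) npad = n - 1;
  NumericMatrix out(n, m);
  std::vector<double> z(n + 2 * npad);
  for (int c = 0; c < m; ++c) {
    for (int i = 0; i < npad; ++i) z[i] = 2.0 * x(0, c) - x(npad - i, c);
    for (int i = 0; i < n; ++i) z[npad + i] = x(i, c);
    for (int i = 0; i < npad; ++i)
      z[npad + n + i] = 2.0 * x(n - 1, c) - x(n - 2 - i, c);
    iir_forward(z, b, a);
    std::reverse(z.begin(), z.end());
    iir_forward(z, b, a);
    std::reverse(z.begin(), z.end());
    for (int i = 0; i < n; ++i) out(i, c) = z[npad + i];
  }
  return out;
}
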