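#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// Phase lag index matrix from an epoch's instantaneous-phase matrix
// (channels x samples).  PLI(i,j) = |mean_k sign(sin(phi_i[k] - phi_j[k]))|
// with sign(0) contributing exactly 0, as the estimator's definition implies.
// [[Rcpp::export]]
NumericMatrix cpp_pli_from_phases(NumericMatrix phases) {
  const int n = phases.nrow();
  const int m = phases.ncol();
  NumericMatrix out(n, n);
  if (m == 0) stop("phase series must contain at least one sample");
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double acc = 0.0;
      for (int k = 0; k < m; ++k) {
        double s = std::sin(phases(i, k) - phases(j, k));
        if (s > 0.0) acc += 1.0; else if (s < 0.0) acc -= 1.0;
      }
      double v = std::abs(acc / m);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}

// PLI matrix straight from the analytic signal (channels x samples Re/Im):
// sign(sin(phi_i - phi_j)) = sign(Im(z_i * conj(z_j))) =
// sign(im_i * re_j - re_i * im_j), avoiding Arg/sin per sample. Exactly
// equivalent to the phase-difference route wherever the analytic amplitude
// is nonzero.
// [[Rcpp::export]]
NumericMatrix cpp_pli_from_analytic(NumericMatrix re, NumericMatrix im) {
  const int n = re.nrow();
  const int m = re.ncol();
  if (im.nrow() != n || im.ncol() != m) stop("Re/Im shape mismatch");
  if (m == 0) stop("phase series must contain at least one sample");
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double acc = 0.0;
      for (int k = 0; k < m; ++k) {
        double s = im(i, k) * re(j, k) - re(i, k) * im(j, k);
        if (s > 0.0) acc += 1.0; else if (s < 0.0) acc -= 1.0;
      }
      double v = std::abs(acc / m);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}

// Single-channel IIR filtering with zero initial state (direct form I),
// the same recursion signal::filter applies.
static std::vector<double> iir_filter(const NumericVector& b,
                                      const NumericVector& a,
                                      const std::vector<double>& x) {
  const int nb = b.size(), na = a.size(), n = (int)x.size();
  std::vector<double> y(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int k = 0; k < nb && k <= i; ++k) acc += b[k] * x[i - k];
    for (int k = 1; k < na && k <= i; ++k) acc -= a[k] * y[i - k];
    y[i] = acc / a[0];
  }
  return y;
}

// Zero-phase forward-backward filtering of each row of x (channels x
// samples), replicating signal::filtfilt: append 2*max(na,nb) zeros,
// filter, reverse, filter, reverse, truncate.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt(NumericVector b, NumericVector a, NumericMatrix x) {
  const int nch = x.nrow();
  const int n = x.ncol();
  const int pad = 2 * std::max(a.size(), b.size());
  NumericMatrix out(nch, n);
  std::vector<double> buf(n + pad);
  for (int c = 0; c < nch; ++c) {
    std::fill(buf.begin(), buf.end(), 0.0);
    for (int i = 0; i < n; ++i) buf[i] = x(c, i);
    std::vector<double> y = iir_filter(b, a, buf);
    std::reverse(y.begin(), y.end());
    y = iir_filter(b, a, y);
    std::reverse(y.begin(), y.end());
    for (int i = 0; i < n; ++i) out(c, i) = y[i];
  }
  return out;
}

struct Edge {
  int i, j;
  double w;
};

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Maximum-weight spanning tree by Kruskal on descending weights.
// Ties broken deterministically by the lexicographically smallest
// (i, j) channel-index pair (stable sort over edges generated in
// row-major upper-triangle order).  Returns an (n-1) x 3 matrix with
// 1-based node indices and the edge weight.
// [[Rcpp::export]]
NumericMatrix cpp_kruskal_max(NumericMatrix w) {
  const int n = w.nrow();
  if (n < 2) stop("need at least 2 nodes");
  std::vector<Edge> edges;
  edges.reserve(n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      edges.push_back({i, j, w(i, j)});
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge& a, const Edge& b) { return a.w > b.w; });
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  NumericMatrix out(n - 1, 3);
  int k = 0;
  for (const Edge& e : edges) {
    int a = uf_find(parent, e.i);
    int b = uf_find(parent, e.j);
    if (a != b) {
      parent[a] = b;
      out(k, 0) = e.i + 1;
      out(k, 1) = e.j + 1;
      out(k, 2) = e.w;
      if (++k == n - 1) break;
    }
  }
  if (k != n - 1) stop("input matrix does not yield a spanning tree");
  return out;
}

// Nodal tree measures for an n-node tree given as 1-based edge endpoints:
// raw degree, raw betweenness (count of unordered pairs of other nodes
// whose unique path passes through the node), raw eccentricity in hops.
// Betweenness uses the tree property: removing a node splits the tree
// into components; pairs through the node = (S^2 - sum c_t^2) / 2 where
// c_t are component sizes and S their total.
// [[Rcpp::export]]
List cpp_tree_metrics(IntegerVector u, IntegerVector v, int n) {
  const int m = u.size();
  if (m != n - 1) stop("a tree on n nodes must have n-1 edges");
  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < m; ++e) {
    int a = u[e] - 1, b = v[e] - 1;
    if (a < 0 || b < 0 || a >= n || b >= n || a == b) stop("invalid edge");
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  IntegerVector deg(n), ecc(n);
  NumericVector bc(n);
  std::vector<int> dist(n), q(n);
  for (int s = 0; s < n; ++s) {
    deg[s] = (int)adj[s].size();
    // BFS for eccentricity
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int head = 0, tail = 0;
    q[tail++] = s;
    int emax = 0;
    while (head < tail) {
      int x = q[head++];
      for (int y : adj[x]) {
        if (dist[y] < 0) {
          dist[y] = dist[x] + 1;
          if (dist[y] > emax) emax = dist[y];
          q[tail++] = y;
        }
      }
    }
    if (tail != n) stop("graph is not connected");
    ecc[s] = emax;
    // component sizes after removing s
    double S = 0.0, sq = 0.0;
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    for (int root : adj[s]) {
      if (dist[root] >= 0) continue;
      dist[root] = 1;
      int h2 = 0, t2 = 0, cnt = 0;
      q[t2++] = root;
      while (h2 < t2) {
        int x = q[h2++];
        ++cnt;
        for (int y : adj[x]) {
          if (dist[y] < 0) {
            dist[y] = 1;
            q[t2++] = y;
          }
        }
      }
      S += cnt;
      sq += (double)cnt * cnt;
    }
    bc[s] = (S * S - sq) / 2.0;
  }
  return List::create(_["degree_raw"] = deg, _["bc_pairs"] = bc,
                      _["ecc_raw"] = ecc);
}

// One-shot spanning-tree summary of a symmetric weight matrix: Kruskal MST,
// nodal measures, and the eight global measures, avoiding per-epoch R
// overhead in the cohort pipeline. Global order: max_degree, max_bc, ecc,
// diameter, leaf, th, kappa, r (r = NA for degenerate degree variance,
// th = NA when max_bc = 0, i.e. n = 2).
// [[Rcpp::export]]
List cpp_mst_summary(NumericMatrix w) {
  NumericMatrix el = cpp_kruskal_max(w);
  const int n = w.nrow();
  IntegerVector u(n - 1), v(n - 1);
  for (int e = 0; e < n - 1; ++e) {
    u[e] = (int)el(e, 0);
    v[e] = (int)el(e, 1);
  }
  List nm = cpp_tree_metrics(u, v, n);
  IntegerVector deg = nm["degree_raw"];
  NumericVector bcp = nm["bc_pairs"];
  IntegerVector ecc = nm["ecc_raw"];
  const double npairs = (double)(n - 1) * (n - 2) / 2.0;
  NumericVector degree(n), bc(n), eccn(n);
  double max_deg = 0, max_bc = 0, ecc_sum = 0, kap_num = 0, kap_den = 0;
  int diam = 0, leaves = 0;
  for (int i = 0; i < n; ++i) {
    degree[i] = (double)deg[i] / (n - 1);
    bc[i] = npairs > 0 ? bcp[i] / npairs : 0.0;
    eccn[i] = (double)ecc[i] / (n - 1);
    if (degree[i] > max_deg) max_deg = degree[i];
    if (bc[i] > max_bc) max_bc = bc[i];
    ecc_sum += eccn[i];
    if (ecc[i] > diam) diam = ecc[i];
    if (deg[i] == 1) ++leaves;
    kap_num += (double)deg[i] * deg[i];
    kap_den += deg[i];
  }
  double th = max_bc > 0 ? leaves / (2.0 * (n - 1) * max_bc) : NA_REAL;
  // degree correlation over the symmetrized edge list
  double sx = 0, sxx = 0, sxy = 0;
  const int m2 = 2 * (n - 1);
  for (int e = 0; e < n - 1; ++e) {
    double a = deg[u[e] - 1], b = deg[v[e] - 1];
    sx += a + b;
    sxx += a * a + b * b;
    sxy += 2 * a * b;
  }
  double mx = sx / m2;
  double vx = sxx / m2 - mx * mx;
  double cxy = sxy / m2 - mx * mx;
  double r = vx > 1e-15 ? cxy / vx : NA_REAL;
  NumericVector global = NumericVector::create(
      _["max_degree"] = max_deg, _["max_bc"] = max_bc,
      _["ecc"] = ecc_sum / n, _["diameter"] = (double)diam / (n - 1),
      _["leaf"] = (double)leaves / n, _["th"] = th,
      _["kappa"] = kap_num / kap_den, _["r"] = r);
  return List::create(_["global"] = global, _["degree"] = degree,
                      _["bc"] = bc, _["ecc"] = eccn, _["edges"] = el);
}
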