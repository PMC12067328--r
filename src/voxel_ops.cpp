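// Voxel-level primitives for 3D morphometrics: Euclidean distance
// transform, connected-component labeling and marker-based watershed.
// These must operate on true 3D neighborhoods (not slice-wise), hence
// compiled kernels behind thin R wrappers.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform of a sampled function (lower envelope
// of parabolas, Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  // only finite parabolas enter the envelope; all-infinite input stays so
  int q0 = 0;
  while (q0 < n && f[q0] == INF) q0++;
  if (q0 == n) {
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; q++) {
    if (f[q] == INF) continue;
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance from every foreground voxel to the nearest
// background voxel.  Foreground with no background anywhere -> Inf.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along axis 1 (fastest-varying)
  for (int k3 = 0; k3 < n3; k3++)
    for (int k2 = 0; k2 < n2; k2++) {
      R_xlen_t base = (R_xlen_t)k3 * n1 * n2 + (R_xlen_t)k2 * n1;
      bool any_fin = false;
      for (int i = 0; i < n1; i++) { f[i] = out[base + i]; if (f[i] < INF) any_fin = true; }
      if (!any_fin) continue;
      dt1d(f, d, v, z, n1);
      for (int i = 0; i < n1; i++) out[base + i] = d[i];
    }
  // pass along axis 2
  for (int k3 = 0; k3 < n3; k3++)
    for (int k1 = 0; k1 < n1; k1++) {
      R_xlen_t base = (R_xlen_t)k3 * n1 * n2 + k1;
      bool any_fin = false;
      for (int i = 0; i < n2; i++) { f[i] = out[base + (R_xlen_t)i * n1]; if (f[i] < INF) any_fin = true; }
      if (!any_fin) continue;
      dt1d(f, d, v, z, n2);
      for (int i = 0; i < n2; i++) out[base + (R_xlen_t)i * n1] = d[i];
    }
  // pass along axis 3
  R_xlen_t sl = (R_xlen_t)n1 * n2;
  for (int k2 = 0; k2 < n2; k2++)
    for (int k1 = 0; k1 < n1; k1++) {
      R_xlen_t base = (R_xlen_t)k2 * n1 + k1;
      bool any_fin = false;
      for (int i = 0; i < n3; i++) { f[i] = out[base + (R_xlen_t)i * sl]; if (f[i] < INF) any_fin = true; }
      if (!any_fin) continue;
      dt1d(f, d, v, z, n3);
      for (int i = 0; i < n3; i++) out[base + (R_xlen_t)i * sl] = d[i];
    }
  return out;
}

static int neigh_offsets(int n1, int n2, int n3, bool full,
                         std::vector<R_xlen_t>& off,
                         std::vector<int>& d1, std::vector<int>& d2,
                         std::vector<int>& d3) {
  off.clear(); d1.clear(); d2.clear(); d3.clear();
  for (int a = -1; a <= 1; a++)
    for (int b = -1; b <= 1; b++)
      for (int c = -1; c <= 1; c++) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (!full && manh != 1) continue;
        off.push_back((R_xlen_t)a + (R_xlen_t)b * n1 + (R_xlen_t)c * n1 * n2);
        d1.push_back(a); d2.push_back(b); d3.push_back(c);
      }
  (void)n3;
  return (int)off.size();
}

// Connected-component labeling, 6- or 26-connectivity.  Components are
// numbered 1..K in order of their first voxel in column-major scan, so
// labeling is deterministic.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims, bool full) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> off; std::vector<int> d1, d2, d3;
  int nn = neigh_offsets(n1, n2, n3, full, off, d1, d2, d3);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int p1 = (int)(p % n1), p2 = (int)((p / n1) % n2), p3 = (int)(p / ((R_xlen_t)n1 * n2));
      for (int j = 0; j < nn; j++) {
        int q1 = p1 + d1[j], q2 = p2 + d2[j], q3 = p3 + d3[j];
        if (q1 < 0 || q1 >= n1 || q2 < 0 || q2 >= n2 || q3 < 0 || q3 >= n3) continue;
        R_xlen_t q = p + off[j];
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

struct WsNode {
  double prio;      // flood priority (higher first)
  R_xlen_t order;   // FIFO tie-break for determinism
  R_xlen_t vox;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio < b.prio;
    return a.order > b.order;
  }
};

// Marker-based watershed by priority flooding: flood the mask from the
// labeled marker voxels in order of decreasing priority (here the
// Euclidean distance transform), assigning each voxel the label of the
// basin that reaches it first.  Every mask voxel receives a label.
// [[Rcpp::export(name = ".watershed3d_cpp")]]
IntegerVector watershed3d_cpp(NumericVector prio, IntegerVector markers,
                              LogicalVector mask, IntegerVector dims,
                              bool full) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> off; std::vector<int> d1, d2, d3;
  int nn = neigh_offsets(n1, n2, n3, full, off, d1, d2, d3);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  R_xlen_t counter = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push(WsNode{prio[i], counter++, i});
    }
  }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    R_xlen_t p = nd.vox;
    int p1 = (int)(p % n1), p2 = (int)((p / n1) % n2), p3 = (int)(p / ((R_xlen_t)n1 * n2));
    for (int j = 0; j < nn; j++) {
      int q1 = p1 + d1[j], q2 = p2 + d2[j], q3 = p3 + d3[j];
      if (q1 < 0 || q1 >= n1 || q2 < 0 || q2 >= n2 || q3 < 0 || q3 >= n3) continue;
      R_xlen_t q = p + off[j];
      if (mask[q] && lab[q] == 0) {
        lab[q] = lab[p];
        pq.push(WsNode{prio[q], counter++, q});
      }
    }
  }
  return lab;
}
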