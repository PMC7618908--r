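#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- union-find ------------------------------------------------------------
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Threshold-free cluster enhancement on a vertex-adjacency graph.
// For every threshold h = dh, 2dh, ..., max(stat), vertices with stat >= h
// are grouped into connected components; each member vertex accumulates
// area(component)^E * h^H * dh, areas summed in ascending vertex order so the
// result is bit-for-bit reproducible by an independent R sweep.
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerMatrix edges,
                       NumericVector areas, double H, double E, double dh) {
  const int n = stat.size();
  const int ne = edges.nrow();
  NumericVector out(n);
  double mx = 0.0;
  for (int i = 0; i < n; ++i) if (stat[i] > mx) mx = stat[i];
  if (mx <= 0.0 || dh <= 0.0) return out;
  int nh = (int)std::floor(mx / dh + 1e-12);
  std::vector<int> parent(n);
  std::vector<double> acc(n);
  for (int k = 1; k <= nh; ++k) {
    double h = k * dh;
    for (int i = 0; i < n; ++i) parent[i] = i;
    for (int e = 0; e < ne; ++e) {
      int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
      if (stat[a] >= h && stat[b] >= h) uf_union(parent, a, b);
    }
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int i = 0; i < n; ++i)
      if (stat[i] >= h) acc[uf_find(parent, i)] += areas[i];
    double hh = std::pow(h, H);
    // pow(area, E) evaluated once per component root, not per vertex
    for (int i = 0; i < n; ++i)
      if (stat[i] >= h && parent[i] == i) acc[i] = std::pow(acc[i], E);
    for (int i = 0; i < n; ++i)
      if (stat[i] >= h)
        out[i] += acc[uf_find(parent, i)] * hh * dh;
  }
  return out;
}

// ---- spherical point location ---------------------------------------------
// Barycentric coordinates of q in the planar triangle (a, b, c) under radial
// (gnomonic) projection: solve [a b c] x = q; inside iff all x >= -tol.
static bool bary(const double* V, int a, int b, int c, const double* q,
                 double* w, double tol) {
  double m[9] = {V[a], V[a + 1], V[a + 2],
                 V[b], V[b + 1], V[b + 2],
                 V[c], V[c + 1], V[c + 2]};
  // columns are the three vertices; solve by Cramer
  double det = m[0] * (m[4] * m[8] - m[5] * m[7])
             - m[3] * (m[1] * m[8] - m[2] * m[7])
             + m[6] * (m[1] * m[5] - m[2] * m[4]);
  if (std::fabs(det) < 1e-300) return false;
  double d0 = q[0] * (m[4] * m[8] - m[5] * m[7])
            - m[3] * (q[1] * m[8] - q[2] * m[7])
            + m[6] * (q[1] * m[5] - q[2] * m[4]);
  double d1 = m[0] * (q[1] * m[8] - q[2] * m[7])
            - q[0] * (m[1] * m[8] - m[2] * m[7])
            + m[6] * (m[1] * q[2] - m[2] * q[1]);
  double d2 = m[0] * (m[4] * q[2] - m[5] * q[1])
            - m[3] * (m[1] * q[2] - m[2] * q[1])
            + q[0] * (m[1] * m[5] - m[2] * m[4]);
  double b0 = d0 / det, b1 = d1 / det, b2 = d2 / det;
  double s = b0 + b1 + b2;
  if (s <= 0) return false;
  w[0] = b0 / s; w[1] = b1 / s; w[2] = b2 / s;
  return b0 >= -tol * s && b1 >= -tol * s && b2 >= -tol * s;
}

// Locate each query direction in a spherical triangulation. Returns the
// containing triangle (1-based), normalised barycentric weights, and a flag
// for queries resolved by the nearest-triangle fallback.
// [[Rcpp::export(name = ".locate_points_cpp")]]
List locate_points_cpp(NumericMatrix verts, IntegerMatrix tris,
                       NumericMatrix queries) {
  const int nv = verts.nrow(), nt = tris.nrow(), nq = queries.nrow();
  // column-major flat copy for fast row access
  std::vector<double> V(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) V[3 * i + k] = verts(i, k);
  // vertex -> incident triangles
  std::vector<std::vector<int> > vt(nv);
  for (int t = 0; t < nt; ++t)
    for (int k = 0; k < 3; ++k) vt[tris(t, k) - 1].push_back(t);
  IntegerVector tri_out(nq);
  NumericMatrix w_out(nq, 3);
  LogicalVector fallback(nq);
  const double tol = 1e-10;
  std::vector<char> seen(nt, 0);
  std::vector<int> touched;
  for (int q = 0; q < nq; ++q) {
    double Q[3] = {queries(q, 0), queries(q, 1), queries(q, 2)};
    // nearest vertex by max dot product
    int best = 0; double bd = -2.0;
    for (int i = 0; i < nv; ++i) {
      double d = V[3 * i] * Q[0] + V[3 * i + 1] * Q[1] + V[3 * i + 2] * Q[2];
      if (d > bd) { bd = d; best = i; }
    }
    touched.clear();
    int found = -1;
    double w[3];
    // ring 1: triangles of the nearest vertex; ring 2: triangles of their vertices
    std::vector<int> frontier = vt[best];
    for (int ring = 0; ring < 2 && found < 0; ++ring) {
      std::vector<int> next;
      for (size_t f = 0; f < frontier.size(); ++f) {
        int t = frontier[f];
        if (seen[t]) continue;
        seen[t] = 1; touched.push_back(t);
        int a = 3 * (tris(t, 0) - 1), b = 3 * (tris(t, 1) - 1),
            c = 3 * (tris(t, 2) - 1);
        if (found < 0 && bary(&V[0], a, b, c, Q, w, tol)) { found = t; break; }
        if (ring == 0)
          for (int k = 0; k < 3; ++k) {
            const std::vector<int>& more = vt[tris(t, k) - 1];
            next.insert(next.end(), more.begin(), more.end());
          }
      }
      frontier = next;
    }
    for (size_t f = 0; f < touched.size(); ++f) seen[touched[f]] = 0;
    if (found < 0) {
      // nearest-triangle fallback: maximise the minimum barycentric coordinate
      fallback[q] = true;
      double bestmin = -1e300; int bt = 0; double bw[3] = {1, 0, 0};
      for (int t = 0; t < nt; ++t) {
        int a = 3 * (tris(t, 0) - 1), b = 3 * (tris(t, 1) - 1),
            c = 3 * (tris(t, 2) - 1);
        double ww[3];
        if (!bary(&V[0], a, b, c, Q, ww, 1e300)) continue;
        double mn = std::min(ww[0], std::min(ww[1], ww[2]));
        if (mn > bestmin) {
          bestmin = mn; bt = t; bw[0] = ww[0]; bw[1] = ww[1]; bw[2] = ww[2];
        }
      }
      // clamp outside weights to the triangle and renormalise
      double s = 0;
      for (int k = 0; k < 3; ++k) { if (bw[k] < 0) bw[k] = 0; s += bw[k]; }
      found = bt;
      w[0] = bw[0] / s; w[1] = bw[1] / s; w[2] = bw[2] / s;
    }
    tri_out[q] = found + 1;
    w_out(q, 0) = w[0]; w_out(q, 1) = w[1]; w_out(q, 2) = w[2];
  }
  return List::create(_["triangle"] = tri_out, _["weights"] = w_out,
                      _["fallback"] = fallback);
}
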