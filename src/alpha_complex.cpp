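// Weighted alpha-complex construction for small-to-medium atomic point sets.
//
// A tetrahedron belongs to the regular (weighted Delaunay) triangulation iff
// its orthosphere is empty: every other weighted point has positive power
// distance to it.  It belongs to the alpha complex iff additionally its
// orthoradius^2 <= alpha.  Surface atoms are the vertices incident to a
// boundary facet (a facet shared by exactly one cell) or incident to no cell
// at all; solid angles are accumulated over incident cells.
//
// Degeneracies (cospherical quintuples, e.g. lattice inputs) are resolved by
// a deterministic symbolic perturbation keyed on atom serial: predicates are
// evaluated on minutely jittered copies of the coordinates while all reported
// angles are computed on the unperturbed coordinates, so results are
// deterministic and rigid-motion invariant to machine precision.

#include <Rcpp.h>
#include <array>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double jitter_component(int serial, int dim, double scale) {
  // cheap deterministic hash; reproduced verbatim by the R-side oracle
  return scale * std::sin(0.5 + serial * 12.9898 + dim * 78.233);
}

struct OrthoBall {
  double cx, cy, cz, r2;
  bool ok;
};

// orthocenter of four weighted points: |c - p_i|^2 - w2_i equal for all i
static OrthoBall orthoball(const std::vector<double>& x,
                           const std::vector<double>& y,
                           const std::vector<double>& z,
                           const NumericVector& w2,
                           int i, int j, int k, int l) {
  OrthoBall ob; ob.ok = false;
  double a11 = x[j]-x[i], a12 = y[j]-y[i], a13 = z[j]-z[i];
  double a21 = x[k]-x[i], a22 = y[k]-y[i], a23 = z[k]-z[i];
  double a31 = x[l]-x[i], a32 = y[l]-y[i], a33 = z[l]-z[i];
  double qi = x[i]*x[i] + y[i]*y[i] + z[i]*z[i] - w2[i];
  double b1 = 0.5 * ((x[j]*x[j] + y[j]*y[j] + z[j]*z[j] - w2[j]) - qi);
  double b2 = 0.5 * ((x[k]*x[k] + y[k]*y[k] + z[k]*z[k] - w2[k]) - qi);
  double b3 = 0.5 * ((x[l]*x[l] + y[l]*y[l] + z[l]*z[l] - w2[l]) - qi);
  double det = a11*(a22*a33 - a23*a32) - a12*(a21*a33 - a23*a31)
             + a13*(a21*a32 - a22*a31);
  double scale = std::fabs(a11) + std::fabs(a12) + std::fabs(a13)
               + std::fabs(a21) + std::fabs(a22) + std::fabs(a23)
               + std::fabs(a31) + std::fabs(a32) + std::fabs(a33);
  if (std::fabs(det) < 1e-13 * scale * scale * scale + 1e-300) return ob;
  ob.cx = ( b1*(a22*a33 - a23*a32) - a12*(b2*a33 - a23*b3)
          + a13*(b2*a32 - a22*b3)) / det;
  ob.cy = ( a11*(b2*a33 - a23*b3) - b1*(a21*a33 - a23*a31)
          + a13*(a21*b3 - b2*a31)) / det;
  ob.cz = ( a11*(a22*b3 - b2*a32) - a12*(a21*b3 - b2*a31)
          + b1*(a21*a32 - a22*a31)) / det;
  double dx = ob.cx - x[i], dy = ob.cy - y[i], dz = ob.cz - z[i];
  ob.r2 = dx*dx + dy*dy + dz*dz - w2[i];
  ob.ok = true;
  return ob;
}

// interior dihedral angle along edge (v,a) of tetrahedron (v,a,b,c)
static double dihedral(const double* v, const double* a,
                       const double* b, const double* c) {
  double e[3]  = {a[0]-v[0], a[1]-v[1], a[2]-v[2]};
  double u[3]  = {b[0]-v[0], b[1]-v[1], b[2]-v[2]};
  double w[3]  = {c[0]-v[0], c[1]-v[1], c[2]-v[2]};
  double n1[3] = {e[1]*u[2]-e[2]*u[1], e[2]*u[0]-e[0]*u[2], e[0]*u[1]-e[1]*u[0]};
  double n2[3] = {e[1]*w[2]-e[2]*w[1], e[2]*w[0]-e[0]*w[2], e[0]*w[1]-e[1]*w[0]};
  double dot = n1[0]*n2[0] + n1[1]*n2[1] + n1[2]*n2[2];
  double cr[3] = {n1[1]*n2[2]-n1[2]*n2[1], n1[2]*n2[0]-n1[0]*n2[2],
                  n1[0]*n2[1]-n1[1]*n2[0]};
  double s = std::sqrt(cr[0]*cr[0] + cr[1]*cr[1] + cr[2]*cr[2]);
  return std::atan2(s, dot);
}

// [[Rcpp::export(name = ".alpha_complex_cpp")]]
List alpha_complex_cpp(NumericMatrix pos, NumericVector w2,
                       IntegerVector serial, double alpha,
                       double jitter_scale) {
  const int n = pos.nrow();
  if (n < 4) stop("need at least 4 points");

  std::vector<double> x(n), y(n), z(n);       // perturbed, for predicates
  std::vector<double> x0(n), y0(n), z0(n);    // original, for angles
  for (int i = 0; i < n; ++i) {
    x0[i] = pos(i, 0); y0[i] = pos(i, 1); z0[i] = pos(i, 2);
    x[i] = x0[i] + jitter_component(serial[i], 1, jitter_scale);
    y[i] = y0[i] + jitter_component(serial[i], 2, jitter_scale);
    z[i] = z0[i] + jitter_component(serial[i], 3, jitter_scale);
  }

  double w2max = *std::max_element(w2.begin(), w2.end());
  std::vector<std::array<int,4>> cells;

  if (alpha + w2max > 0) {
    // any vertex of an alpha cell lies within sqrt(alpha + w2_i) of the
    // orthocenter, so cell edges are bounded by 2*sqrt(alpha + w2max)
    double reach = 2.0 * std::sqrt(alpha + w2max);
    double reach2 = reach * reach * (1.0 + 1e-9);
    std::vector<std::vector<int>> nb(n);
    std::vector<std::vector<char>> adj(n, std::vector<char>(n, 0));
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = x[i]-x[j], dy = y[i]-y[j], dz = z[i]-z[j];
        if (dx*dx + dy*dy + dz*dz <= reach2) {
          nb[i].push_back(j);
          adj[i][j] = adj[j][i] = 1;
        }
      }

    for (int i = 0; i < n; ++i) {
      const std::vector<int>& ni = nb[i];
      const size_t m = ni.size();
      for (size_t a = 0; a < m; ++a) {
        int j = ni[a];
        for (size_t b = a + 1; b < m; ++b) {
          int k = ni[b];
          if (!adj[j][k]) continue;
          for (size_t c = b + 1; c < m; ++c) {
            int l = ni[c];
            if (!adj[j][l] || !adj[k][l]) continue;
            OrthoBall ob = orthoball(x, y, z, w2, i, j, k, l);
            if (!ob.ok || ob.r2 > alpha) continue;
            bool empty = true;
            for (int q = 0; q < n; ++q) {
              if (q == i || q == j || q == k || q == l) continue;
              double dx = x[q]-ob.cx, dy = y[q]-ob.cy, dz = z[q]-ob.cz;
              if (dx*dx + dy*dy + dz*dz - w2[q] < ob.r2) { empty = false; break; }
            }
            if (empty) cells.push_back({i, j, k, l});
          }
        }
      }
    }
  }

  const int m = (int) cells.size();
  std::map<std::array<int,3>, int> facet_count;
  for (int t = 0; t < m; ++t) {
    const std::array<int,4>& c = cells[t];
    for (int f = 0; f < 4; ++f) {
      std::array<int,3> tri;
      int p = 0;
      for (int v = 0; v < 4; ++v) if (v != f) tri[p++] = c[v];
      std::sort(tri.begin(), tri.end());
      facet_count[tri]++;
    }
  }

  std::vector<std::array<int,3>> boundary;
  for (std::map<std::array<int,3>, int>::const_iterator it = facet_count.begin();
       it != facet_count.end(); ++it)
    if (it->second == 1) boundary.push_back(it->first);

  NumericVector omega(n, 0.0);
  IntegerVector n_incident(n, 0);
  for (int t = 0; t < m; ++t) {
    const std::array<int,4>& c = cells[t];
    for (int v = 0; v < 4; ++v) {
      int iv = c[v];
      int rest[3]; int p = 0;
      for (int u = 0; u < 4; ++u) if (u != v) rest[p++] = c[u];
      double V[3]  = {x0[iv], y0[iv], z0[iv]};
      double A[3]  = {x0[rest[0]], y0[rest[0]], z0[rest[0]]};
      double B[3]  = {x0[rest[1]], y0[rest[1]], z0[rest[1]]};
      double C[3]  = {x0[rest[2]], y0[rest[2]], z0[rest[2]]};
      double om = dihedral(V, A, B, C) + dihedral(V, B, A, C)
                + dihedral(V, C, A, B) - M_PI;
      omega[iv] += om;
      n_incident[iv] += 1;
    }
  }

  LogicalVector on_surface(n, false);
  for (size_t f = 0; f < boundary.size(); ++f)
    for (int v = 0; v < 3; ++v) on_surface[boundary[f][v]] = true;
  for (int i = 0; i < n; ++i)
    if (n_incident[i] == 0) on_surface[i] = true;

  IntegerMatrix tetra(m, 4);
  for (int t = 0; t < m; ++t)
    for (int v = 0; v < 4; ++v) tetra(t, v) = cells[t][v] + 1;
  IntegerMatrix bf((int) boundary.size(), 3);
  for (size_t f = 0; f < boundary.size(); ++f)
    for (int v = 0; v < 3; ++v) bf((int) f, v) = boundary[f][v] + 1;

  return List::create(_["tetra"] = tetra,
                      _["boundary_facets"] = bf,
                      _["omega"] = omega,
                      _["n_incident"] = n_incident,
                      _["on_surface"] = on_surface);
}
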