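// Incremental 3D Delaunay tessellation (Bowyer-Watson with an infinite vertex).
//
// Cells are tetrahedra over the input sites plus one symbolic vertex "at
// infinity"; every convex-hull facet is the finite facet of one infinite
// cell.  Point location is by linear scan over live cells (n is a few
// hundred for C-alpha chains, so no walk structure is needed), conflict
// regions by breadth-first search, and cavity retriangulation by facet
// gluing.  Predicates are double precision with a static relative-error
// filter; near-ties fall back to conservative (not-in-conflict) handling.

#include <Rcpp.h>
#include <array>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const int INF_V = -1;

struct Cell {
  int v[4];   // vertex indices, INF_V for the infinite vertex
  int nb[4];  // nb[i] = cell opposite v[i]
  bool alive;
};

// relative tolerance for the determinant filters
static const double REL_EPS = 1e-10;

// orientation of d w.r.t. plane (a,b,c): det[a-d; b-d; c-d]
// mag receives a bound on the rounding magnitude of the expansion
static double orient3d(const std::vector<double> &P, int a, int b, int c,
                       int d, double &mag) {
  const double adx = P[3 * a] - P[3 * d], ady = P[3 * a + 1] - P[3 * d + 1],
               adz = P[3 * a + 2] - P[3 * d + 2];
  const double bdx = P[3 * b] - P[3 * d], bdy = P[3 * b + 1] - P[3 * d + 1],
               bdz = P[3 * b + 2] - P[3 * d + 2];
  const double cdx = P[3 * c] - P[3 * d], cdy = P[3 * c + 1] - P[3 * d + 1],
               cdz = P[3 * c + 2] - P[3 * d + 2];
  const double m1 = bdy * cdz - bdz * cdy;
  const double m2 = bdz * cdx - bdx * cdz;
  const double m3 = bdx * cdy - bdy * cdx;
  mag = std::fabs(adx) * (std::fabs(bdy * cdz) + std::fabs(bdz * cdy)) +
        std::fabs(ady) * (std::fabs(bdz * cdx) + std::fabs(bdx * cdz)) +
        std::fabs(adz) * (std::fabs(bdx * cdy) + std::fabs(bdy * cdx));
  return adx * m1 + ady * m2 + adz * m3;
}

// insphere: for a positively oriented (a,b,c,d), returns > 0 iff e lies
// strictly inside their circumsphere
static double insphere(const std::vector<double> &P, int a, int b, int c,
                       int d, int e, double &mag) {
  double ex = P[3 * e], ey = P[3 * e + 1], ez = P[3 * e + 2];
  double r[4][4], rabs[4][4];
  int idx[4] = {a, b, c, d};
  for (int i = 0; i < 4; ++i) {
    double dx = P[3 * idx[i]] - ex, dy = P[3 * idx[i] + 1] - ey,
           dz = P[3 * idx[i] + 2] - ez;
    r[i][0] = dx; r[i][1] = dy; r[i][2] = dz;
    r[i][3] = dx * dx + dy * dy + dz * dz;
    for (int j = 0; j < 4; ++j) rabs[i][j] = std::fabs(r[i][j]);
  }
  // 4x4 determinant by cofactor expansion along the last column
  double det = 0.0, m = 0.0;
  for (int i = 0; i < 4; ++i) {
    int rows[3], k = 0;
    for (int j = 0; j < 4; ++j)
      if (j != i) rows[k++] = j;
    const double *p0 = r[rows[0]], *p1 = r[rows[1]], *p2 = r[rows[2]];
    double minor = p0[0] * (p1[1] * p2[2] - p1[2] * p2[1]) -
                   p0[1] * (p1[0] * p2[2] - p1[2] * p2[0]) +
                   p0[2] * (p1[0] * p2[1] - p1[1] * p2[0]);
    double minor_abs =
        rabs[rows[0]][0] * (rabs[rows[1]][1] * rabs[rows[2]][2] +
                            rabs[rows[1]][2] * rabs[rows[2]][1]) +
        rabs[rows[0]][1] * (rabs[rows[1]][0] * rabs[rows[2]][2] +
                            rabs[rows[1]][2] * rabs[rows[2]][0]) +
        rabs[rows[0]][2] * (rabs[rows[1]][0] * rabs[rows[2]][1] +
                            rabs[rows[1]][1] * rabs[rows[2]][0]);
    double sgn = ((i % 2) == 0) ? 1.0 : -1.0;  // (-1)^(i+3) pattern
    det += sgn * r[i][3] * minor;
    m += rabs[i][3] * minor_abs;
  }
  mag = m;
  // det as computed is positive for e INSIDE when (a,b,c,d) is negatively
  // oriented by orient3d above; flip so that the positive-orientation
  // convention of the caller gives inside > 0
  return -det;
}

// strict in-circumcircle test for a point coplanar with triangle (a,b,c)
static bool in_circumcircle_coplanar(const std::vector<double> &P, int a,
                                     int b, int c, int p) {
  // circumcenter of (a,b,c) in 3D
  double ax = P[3 * a], ay = P[3 * a + 1], az = P[3 * a + 2];
  double ux = P[3 * b] - ax, uy = P[3 * b + 1] - ay, uz = P[3 * b + 2] - az;
  double vx = P[3 * c] - ax, vy = P[3 * c + 1] - ay, vz = P[3 * c + 2] - az;
  double uu = ux * ux + uy * uy + uz * uz;
  double vv = vx * vx + vy * vy + vz * vz;
  double uv = ux * vx + uy * vy + uz * vz;
  double den = 2.0 * (uu * vv - uv * uv);
  if (den <= 0) return false;  // degenerate triangle
  double s = (uu * vv - vv * uv) / den;
  double t = (vv * uu - uu * uv) / den;
  double cx = ax + s * ux + t * vx, cy = ay + s * uy + t * vy,
         cz = az + s * uz + t * vz;
  double r2 = (cx - ax) * (cx - ax) + (cy - ay) * (cy - ay) +
              (cz - az) * (cz - az);
  double d2 = (cx - P[3 * p]) * (cx - P[3 * p]) +
              (cy - P[3 * p + 1]) * (cy - P[3 * p + 1]) +
              (cz - P[3 * p + 2]) * (cz - P[3 * p + 2]);
  return d2 < r2 * (1.0 - 1e-12);
}

struct Triangulation {
  const std::vector<double> &P;
  std::vector<Cell> cells;
  explicit Triangulation(const std::vector<double> &pts) : P(pts) {}

  int add_cell(int a, int b, int c, int d) {
    Cell cl;
    cl.v[0] = a; cl.v[1] = b; cl.v[2] = c; cl.v[3] = d;
    cl.nb[0] = cl.nb[1] = cl.nb[2] = cl.nb[3] = -1;
    cl.alive = true;
    cells.push_back(cl);
    return (int)cells.size() - 1;
  }

  // true iff inserting point p must destroy cell ci
  bool in_conflict(int ci, int p) {
    const Cell &cl = cells[ci];
    int infpos = -1;
    for (int i = 0; i < 4; ++i)
      if (cl.v[i] == INF_V) infpos = i;
    if (infpos < 0) {
      double mag;
      double s = insphere(P, cl.v[0], cl.v[1], cl.v[2], cl.v[3], p, mag);
      return s > REL_EPS * mag;
    }
    // infinite cell: finite facet u,v,w; compare side of p against the
    // interior vertex of the finite neighbor across the infinite vertex
    int f[3], k = 0;
    for (int i = 0; i < 4; ++i)
      if (i != infpos) f[k++] = cl.v[i];
    int D = cl.nb[infpos];
    const Cell &dn = cells[D];
    int d = -1;
    for (int i = 0; i < 4; ++i) {
      int vv = dn.v[i];
      if (vv != f[0] && vv != f[1] && vv != f[2]) d = vv;
    }
    double magp, magd;
    double sp = orient3d(P, f[0], f[1], f[2], p, magp);
    double sd = orient3d(P, f[0], f[1], f[2], d, magd);
    if (std::fabs(sp) <= REL_EPS * magp)
      return in_circumcircle_coplanar(P, f[0], f[1], f[2], p);
    return (sp > 0) != (sd > 0);
  }

  void glue_all_faces() {
    std::map<std::array<int, 3>, std::pair<int, int> > fmap;
    for (int ci = 0; ci < (int)cells.size(); ++ci) {
      if (!cells[ci].alive) continue;
      for (int fi = 0; fi < 4; ++fi) {
        std::array<int, 3> key;
        int k = 0;
        for (int j = 0; j < 4; ++j)
          if (j != fi) key[k++] = cells[ci].v[j];
        std::sort(key.begin(), key.end());
        std::map<std::array<int, 3>, std::pair<int, int> >::iterator it =
            fmap.find(key);
        if (it == fmap.end()) {
          fmap[key] = std::make_pair(ci, fi);
        } else {
          cells[ci].nb[fi] = it->second.first;
          cells[it->second.first].nb[it->second.second] = ci;
        }
      }
    }
  }

  void insert(int p) {
    // seed conflict cell by scan
    int seed = -1;
    for (int ci = 0; ci < (int)cells.size(); ++ci) {
      if (cells[ci].alive && in_conflict(ci, p)) { seed = ci; break; }
    }
    if (seed < 0)
      stop("tessellation: point %d conflicts with no cell (degenerate or duplicate input)",
           p + 1);
    // BFS over the conflict region
    std::vector<int> confl;
    std::vector<signed char> state(cells.size(), 0);  // 0 unknown 1 in 2 out
    std::vector<int> stack;
    stack.push_back(seed);
    state[seed] = 1;
    while (!stack.empty()) {
      int ci = stack.back();
      stack.pop_back();
      confl.push_back(ci);
      for (int fi = 0; fi < 4; ++fi) {
        int nbi = cells[ci].nb[fi];
        if (nbi < 0 || state[nbi]) continue;
        state[nbi] = in_conflict(nbi, p) ? 1 : 2;
        if (state[nbi] == 1) stack.push_back(nbi);
      }
    }
    // boundary facets: (facet vertices, outside neighbor, its face index)
    struct BFacet { int w[3]; int nb; int nbf; };
    std::vector<BFacet> bnd;
    for (size_t q = 0; q < confl.size(); ++q) {
      int ci = confl[q];
      for (int fi = 0; fi < 4; ++fi) {
        int nbi = cells[ci].nb[fi];
        if (nbi >= 0 && state[nbi] == 1) continue;  // internal facet
        BFacet bf;
        int k = 0;
        for (int j = 0; j < 4; ++j)
          if (j != fi) bf.w[k++] = cells[ci].v[j];
        bf.nb = nbi;
        bf.nbf = -1;
        if (nbi >= 0) {
          for (int j = 0; j < 4; ++j)
            if (cells[nbi].nb[j] == ci) bf.nbf = j;
        }
        bnd.push_back(bf);
      }
    }
    for (size_t q = 0; q < confl.size(); ++q) cells[confl[q]].alive = false;
    // new cells: p joined to every boundary facet
    std::map<std::pair<int, int>, std::pair<int, int> > pairmap;
    for (size_t q = 0; q < bnd.size(); ++q) {
      int a = bnd[q].w[0], b = bnd[q].w[1], c = bnd[q].w[2];
      int ci;
      bool inf_facet = (a == INF_V || b == INF_V || c == INF_V);
      if (!inf_facet) {
        double mag;
        double s = orient3d(P, a, b, c, p, mag);
        if (s > 0) { int t = b; b = c; c = t; }  // keep orient3d(v0..v3) > 0
        ci = add_cell(a, b, c, p);
      } else {
        ci = add_cell(a, b, c, p);
      }
      // face opposite p is the boundary facet itself
      cells[ci].nb[3] = bnd[q].nb;
      if (bnd[q].nb >= 0) cells[bnd[q].nb].nb[bnd[q].nbf] = ci;
      // remaining faces pair up with sibling new cells
      for (int fi = 0; fi < 3; ++fi) {
        int e[2], k = 0;
        for (int j = 0; j < 3; ++j)
          if (j != fi) e[k++] = cells[ci].v[j];
        std::pair<int, int> key(std::min(e[0], e[1]), std::max(e[0], e[1]));
        std::map<std::pair<int, int>, std::pair<int, int> >::iterator it =
            pairmap.find(key);
        if (it == pairmap.end()) {
          pairmap[key] = std::make_pair(ci, fi);
        } else {
          cells[ci].nb[fi] = it->second.first;
          cells[it->second.first].nb[it->second.second] = ci;
          pairmap.erase(it);
        }
      }
    }
    // re-fix orientation of finite new cells (vertex order was permuted
    // before p was appended, so recheck)
    for (int ci = (int)cells.size() - (int)bnd.size(); ci < (int)cells.size();
         ++ci) {
      Cell &cl = cells[ci];
      bool fin = true;
      for (int j = 0; j < 4; ++j)
        if (cl.v[j] == INF_V) fin = false;
      if (!fin) continue;
      double mag;
      if (orient3d(P, cl.v[0], cl.v[1], cl.v[2], cl.v[3], mag) < 0) {
        int t = cl.v[0]; cl.v[0] = cl.v[1]; cl.v[1] = t;
        int tn = cl.nb[0]; cl.nb[0] = cl.nb[1]; cl.nb[1] = tn;
      }
    }
  }
};

// [[Rcpp::export(name = ".delaunay_tetrahedra")]]
IntegerMatrix delaunay_tetrahedra(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("tessellation needs at least 4 sites, got %d", n);
  std::vector<double> P(3 * n);
  double lo[3], hi[3];
  for (int j = 0; j < 3; ++j) { lo[j] = R_PosInf; hi[j] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      double x = pts(i, j);
      if (!R_finite(x)) stop("non-finite coordinate at site %d", i + 1);
      P[3 * i + j] = x;
      if (x < lo[j]) lo[j] = x;
      if (x > hi[j]) hi[j] = x;
    }
  double scale = 0.0;
  for (int j = 0; j < 3; ++j) scale = std::max(scale, hi[j] - lo[j]);
  if (scale <= 0) stop("all sites coincide: degenerate input");
  double dup2 = 1e-14 * scale * scale;
  for (int i = 0; i < n; ++i)
    for (int k = i + 1; k < n; ++k) {
      double d2 = 0;
      for (int j = 0; j < 3; ++j) {
        double d = P[3 * i + j] - P[3 * k + j];
        d2 += d * d;
      }
      if (d2 <= dup2)
        stop("duplicate sites %d and %d: degenerate input", i + 1, k + 1);
    }

  // initial affinely independent quadruple
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n && i1 < 0; ++i) i1 = i;  // any (no duplicates left)
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double ux = P[3 * i1] - P[3 * i0], uy = P[3 * i1 + 1] - P[3 * i0 + 1],
           uz = P[3 * i1 + 2] - P[3 * i0 + 2];
    double vx = P[3 * i] - P[3 * i0], vy = P[3 * i + 1] - P[3 * i0 + 1],
           vz = P[3 * i + 2] - P[3 * i0 + 2];
    double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz,
           cz = ux * vy - uy * vx;
    if (cx * cx + cy * cy + cz * cz >
        1e-16 * scale * scale * scale * scale) {
      i2 = i;
      break;
    }
  }
  if (i2 < 0) stop("all sites collinear: degenerate input");
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double mag;
    double s = orient3d(P, i0, i1, i2, i, mag);
    if (std::fabs(s) > REL_EPS * mag && mag > 0) { i3 = i; break; }
  }
  if (i3 < 0) stop("all sites coplanar: degenerate input");

  Triangulation T(P);
  {
    double mag;
    int a = i0, b = i1, c = i2, d = i3;
    if (orient3d(P, a, b, c, d, mag) < 0) { int t = b; b = c; c = t; }
    T.add_cell(a, b, c, d);
    T.add_cell(INF_V, b, c, d);  // one infinite cell per facet
    T.add_cell(a, INF_V, c, d);
    T.add_cell(a, b, INF_V, d);
    T.add_cell(a, b, c, INF_V);
    T.glue_all_faces();
  }
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    T.insert(i);
  }

  int m = 0;
  for (size_t ci = 0; ci < T.cells.size(); ++ci) {
    const Cell &cl = T.cells[ci];
    if (!cl.alive) continue;
    bool fin = true;
    for (int j = 0; j < 4; ++j)
      if (cl.v[j] == INF_V) fin = false;
    if (fin) ++m;
  }
  IntegerMatrix out(m, 4);
  int r = 0;
  for (size_t ci = 0; ci < T.cells.size(); ++ci) {
    const Cell &cl = T.cells[ci];
    if (!cl.alive) continue;
    bool fin = true;
    for (int j = 0; j < 4; ++j)
      if (cl.v[j] == INF_V) fin = false;
    if (!fin) continue;
    int vv[4] = {cl.v[0], cl.v[1], cl.v[2], cl.v[3]};
    std::sort(vv, vv + 4);
    for (int j = 0; j < 4; ++j) out(r, j) = vv[j] + 1;
    ++r;
  }
  return out;
}
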