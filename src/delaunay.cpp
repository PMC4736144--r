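// Incremental Bowyer-Watson Delaunay triangulation (2D) / tetrahedralization
// (3D) with a single symbolic vertex at infinity. Hull facets are represented
// as "infinite" simplices (facet + INF); conflict tests against infinite
// simplices reduce to orientation tests on the hull facet, so no finite
// super-simplex coordinates ever enter the predicates.
//
// Predicates are evaluated in long double and reported as determinants
// normalised by the sum of absolute monomials, so a fixed tolerance on the
// normalised value is scale-invariant. Ties (|value| <= tol) are treated as
// "on boundary": cocircular points are NOT carved (ties-outside rule).

#include <Rcpp.h>
#include <array>
#include <vector>
#include <map>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

typedef long double ld;

static const int INF_V = -1;

// ---- normalised predicates ------------------------------------------------

// orient2d(a,b,c) > 0  <=>  a,b,c counter-clockwise
static double orient2d_n(const double* a, const double* b, const double* c) {
  ld ux = (ld)b[0] - a[0], uy = (ld)b[1] - a[1];
  ld vx = (ld)c[0] - a[0], vy = (ld)c[1] - a[1];
  ld t1 = ux * vy, t2 = uy * vx;
  ld det = t1 - t2;
  ld scale = fabsl(t1) + fabsl(t2);
  if (scale == (ld)0) return 0.0;
  return (double)(det / scale);
}

static ld det3(ld ux, ld uy, ld uz, ld vx, ld vy, ld vz,
               ld wx, ld wy, ld wz, ld* scale) {
  ld t1 = ux * (vy * wz), t2 = ux * (vz * wy);
  ld t3 = uy * (vx * wz), t4 = uy * (vz * wx);
  ld t5 = uz * (vx * wy), t6 = uz * (vy * wx);
  if (scale)
    *scale += fabsl(t1) + fabsl(t2) + fabsl(t3) + fabsl(t4) + fabsl(t5) + fabsl(t6);
  return t1 - t2 - t3 + t4 + t5 - t6;
}

// orient3d(a,b,c,d) > 0 <=> positively oriented (canonical unit tetra is +)
static double orient3d_n(const double* a, const double* b, const double* c,
                         const double* d) {
  ld scale = 0;
  ld det = det3((ld)b[0]-a[0], (ld)b[1]-a[1], (ld)b[2]-a[2],
                (ld)c[0]-a[0], (ld)c[1]-a[1], (ld)c[2]-a[2],
                (ld)d[0]-a[0], (ld)d[1]-a[1], (ld)d[2]-a[2], &scale);
  if (scale == (ld)0) return 0.0;
  return (double)(det / scale);
}

// incircle for CCW triangle: > 0 <=> p strictly inside circumcircle
static double incircle2d_n(const double* a, const double* b, const double* c,
                           const double* p) {
  ld ux = (ld)a[0]-p[0], uy = (ld)a[1]-p[1]; ld un = ux*ux + uy*uy;
  ld vx = (ld)b[0]-p[0], vy = (ld)b[1]-p[1]; ld vn = vx*vx + vy*vy;
  ld wx = (ld)c[0]-p[0], wy = (ld)c[1]-p[1]; ld wn = wx*wx + wy*wy;
  ld t1 = ux * (vy * wn), t2 = ux * (vn * wy);
  ld t3 = uy * (vx * wn), t4 = uy * (vn * wx);
  ld t5 = un * (vx * wy), t6 = un * (vy * wx);
  ld det = t1 - t2 - t3 + t4 + t5 - t6;
  ld scale = fabsl(t1) + fabsl(t2) + fabsl(t3) + fabsl(t4) + fabsl(t5) + fabsl(t6);
  if (scale == (ld)0) return 0.0;
  return (double)(det / scale);
}

// insphere for positively oriented tetra: > 0 <=> p strictly inside
static double insphere3d_n(const double* a, const double* b, const double* c,
                           const double* d, const double* p) {
  ld r[4][4];
  const double* pts[4] = {a, b, c, d};
  for (int i = 0; i < 4; ++i) {
    r[i][0] = (ld)pts[i][0] - p[0];
    r[i][1] = (ld)pts[i][1] - p[1];
    r[i][2] = (ld)pts[i][2] - p[2];
    r[i][3] = r[i][0]*r[i][0] + r[i][1]*r[i][1] + r[i][2]*r[i][2];
  }
  ld scale = 0;
  // expand along the norm column (col 4); cofactor signs -,+,-,+
  ld d1 = det3(r[1][0],r[1][1],r[1][2], r[2][0],r[2][1],r[2][2],
               r[3][0],r[3][1],r[3][2], NULL);
  ld d2 = det3(r[0][0],r[0][1],r[0][2], r[2][0],r[2][1],r[2][2],
               r[3][0],r[3][1],r[3][2], NULL);
  ld d3 = det3(r[0][0],r[0][1],r[0][2], r[1][0],r[1][1],r[1][2],
               r[3][0],r[3][1],r[3][2], NULL);
  ld d4 = det3(r[0][0],r[0][1],r[0][2], r[1][0],r[1][1],r[1][2],
               r[2][0],r[2][1],r[2][2], NULL);
  ld det = -r[0][3]*d1 + r[1][3]*d2 - r[2][3]*d3 + r[3][3]*d4;
  scale = fabsl(r[0][3]*d1) + fabsl(r[1][3]*d2) + fabsl(r[2][3]*d3)
        + fabsl(r[3][3]*d4);
  if (scale == (ld)0) return 0.0;
  // sign flip: with this row layout "p inside" comes out negative
  return (double)(-det / scale);
}

// ---- exported predicate helpers -------------------------------------------

// [[Rcpp::export(name = ".cpp_orient")]]
double cpp_orient(NumericMatrix simplex) {
  int d = simplex.ncol();
  std::vector<std::array<double,3> > P(simplex.nrow());
  for (int i = 0; i < simplex.nrow(); ++i)
    for (int j = 0; j < d; ++j) P[i][j] = simplex(i, j);
  if (d == 2) return orient2d_n(P[0].data(), P[1].data(), P[2].data());
  return orient3d_n(P[0].data(), P[1].data(), P[2].data(), P[3].data());
}

// orientation-corrected in-circumball value: > 0 inside regardless of
// vertex ordering of the simplex
// [[Rcpp::export(name = ".cpp_insphere")]]
double cpp_insphere(NumericMatrix simplex, NumericVector q) {
  int d = simplex.ncol();
  std::vector<std::array<double,3> > P(simplex.nrow());
  for (int i = 0; i < simplex.nrow(); ++i)
    for (int j = 0; j < d; ++j) P[i][j] = simplex(i, j);
  double p[3];
  for (int j = 0; j < d; ++j) p[j] = q[j];
  double o, v;
  if (d == 2) {
    o = orient2d_n(P[0].data(), P[1].data(), P[2].data());
    v = incircle2d_n(P[0].data(), P[1].data(), P[2].data(), p);
  } else {
    o = orient3d_n(P[0].data(), P[1].data(), P[2].data(), P[3].data());
    v = insphere3d_n(P[0].data(), P[1].data(), P[2].data(), P[3].data(), p);
  }
  if (o == 0) stop("degenerate simplex");
  return o > 0 ? v : -v;
}

// ---- triangulator ----------------------------------------------------------

struct Simplex {
  std::array<int,4> v;  // d+1 used; INF_V marks the infinite vertex
  bool alive;
};

typedef std::unordered_map<uint64_t, int> FMap;

typedef std::array<int,3> Facet;  // sorted, padded with INT_MAX in 2D

static Facet make_facet(const std::array<int,4>& v, int skip, int d) {
  Facet f; f.fill(INT_MAX);
  int k = 0;
  for (int i = 0; i <= d; ++i) if (i != skip) f[k++] = v[i];
  std::sort(f.begin(), f.begin() + d);
  return f;
}

// pack a sorted facet into one 64-bit key (vertex indices < 2^20)
static inline uint64_t facet_key(const Facet& f, int d) {
  uint64_t k = 0;
  for (int i = 0; i < d; ++i) k = (k << 21) | (uint64_t)(f[i] + 2);
  return k;
}

class Triangulator {
public:
  Triangulator(const NumericMatrix& coords, double tol)
    : pts_(coords), d_(coords.ncol()), tol_(tol) {}

  void run() {
    int n = pts_.nrow();
    if (n < d_ + 1) stop("cannot-triangulate: need at least %d points", d_ + 1);
    std::vector<bool> used(n, false);
    std::vector<int> init = find_initial();
    for (int i : init) used[i] = true;
    make_initial(init);
    for (int i = 0; i < n; ++i) {
      if (!used[i]) insert(i);
    }
  }

  List result() const {
    std::vector<std::array<int,4> > fin;
    std::vector<int> hull_mark(pts_.nrow(), 0);
    for (const Simplex& s : S_) {
      if (!s.alive) continue;
      if (is_infinite(s)) {
        for (int i = 0; i <= d_; ++i)
          if (s.v[i] != INF_V) hull_mark[s.v[i]] = 1;
      } else {
        fin.push_back(s.v);
      }
    }
    IntegerMatrix simp(fin.size(), d_ + 1);
    for (size_t r = 0; r < fin.size(); ++r)
      for (int c = 0; c <= d_; ++c) simp(r, c) = fin[r][c] + 1;
    std::vector<int> hull;
    for (int i = 0; i < (int)hull_mark.size(); ++i)
      if (hull_mark[i]) hull.push_back(i + 1);
    return List::create(_["simplices"] = simp, _["hull"] = wrap(hull));
  }

private:
  const NumericMatrix& pts_;
  int d_;
  double tol_;
  std::vector<Simplex> S_;

  // NumericMatrix is column-major; copy the row out
  void get(int i, double* out) const {
    for (int j = 0; j < d_; ++j) out[j] = pts_(i, j);
  }

  bool is_infinite(const Simplex& s) const {
    for (int i = 0; i <= d_; ++i) if (s.v[i] == INF_V) return true;
    return false;
  }

  double orient_idx(const int* v, int pidx) const {
    double P[4][3];
    for (int i = 0; i < d_; ++i) get(v[i], P[i]);
    get(pidx, P[d_]);
    if (d_ == 2) return orient2d_n(P[0], P[1], P[2]);
    return orient3d_n(P[0], P[1], P[2], P[3]);
  }

  double insphere_idx(const std::array<int,4>& v, int pidx) const {
    double P[4][3], q[3];
    for (int i = 0; i <= d_; ++i) get(v[i], P[i]);
    get(pidx, q);
    if (d_ == 2) return incircle2d_n(P[0], P[1], P[2], q);
    return insphere3d_n(P[0], P[1], P[2], P[3], q);
  }

  std::vector<int> find_initial() const {
    int n = pts_.nrow();
    std::vector<int> init;
    init.push_back(0);
    // second point: any distinct (duplicates rejected upstream)
    init.push_back(1);
    // third: first non-collinear
    int v3 = -1;
    for (int k = 2; k < n; ++k) {
      int tri[2] = {init[0], init[1]};
      double P[3][3];
      get(tri[0], P[0]); get(tri[1], P[1]); get(k, P[2]);
      double o = (d_ == 2) ? orient2d_n(P[0], P[1], P[2])
                           : collinear3(P[0], P[1], P[2]);
      if (std::fabs(o) > tol_) { v3 = k; break; }
    }
    if (v3 < 0) stop("cannot-triangulate: all points collinear");
    init.push_back(v3);
    if (d_ == 3) {
      int v4 = -1;
      for (int k = 2; k < n; ++k) {
        if (k == v3) continue;
        double P[4][3];
        get(init[0], P[0]); get(init[1], P[1]); get(init[2], P[2]); get(k, P[3]);
        if (std::fabs(orient3d_n(P[0], P[1], P[2], P[3])) > tol_) { v4 = k; break; }
      }
      if (v4 < 0) stop("cannot-triangulate: all points coplanar");
      init.push_back(v4);
    }
    return init;
  }

  // normalised "non-collinearity" measure for 3 points in 3D
  static double collinear3(const double* a, const double* b, const double* c) {
    ld ux = (ld)b[0]-a[0], uy = (ld)b[1]-a[1], uz = (ld)b[2]-a[2];
    ld vx = (ld)c[0]-a[0], vy = (ld)c[1]-a[1], vz = (ld)c[2]-a[2];
    ld cx = uy*vz - uz*vy, cy = uz*vx - ux*vz, cz = ux*vy - uy*vx;
    ld num = sqrtl(cx*cx + cy*cy + cz*cz);
    ld den = sqrtl((ux*ux+uy*uy+uz*uz) * (vx*vx+vy*vy+vz*vz));
    if (den == (ld)0) return 0.0;
    return (double)(num / den);
  }

  void make_initial(const std::vector<int>& init) {
    Simplex s0; s0.alive = true; s0.v.fill(INT_MAX);
    for (int i = 0; i <= d_; ++i) s0.v[i] = init[i];
    // orient positively
    if (orient_of(s0.v) < 0) std::swap(s0.v[0], s0.v[1]);
    S_.push_back(s0);
    for (int i = 0; i <= d_; ++i) {
      Simplex inf; inf.alive = true; inf.v.fill(INT_MAX);
      int k = 0;
      for (int j = 0; j <= d_; ++j) if (j != i) inf.v[k++] = s0.v[j];
      inf.v[d_] = INF_V;
      S_.push_back(inf);
    }
  }

  double orient_of(const std::array<int,4>& v) const {
    double P[4][3];
    for (int i = 0; i <= d_; ++i) get(v[i], P[i]);
    if (d_ == 2) return orient2d_n(P[0], P[1], P[2]);
    return orient3d_n(P[0], P[1], P[2], P[3]);
  }

  void insert(int ip) {
    // hull facet -> the finite simplex owning it (for visibility tests)
    FMap fmap;
    std::vector<int> alive_idx;
    for (int si = 0; si < (int)S_.size(); ++si) {
      if (!S_[si].alive) continue;
      alive_idx.push_back(si);
      if (is_infinite(S_[si])) continue;
      for (int i = 0; i <= d_; ++i) {
        Facet f = make_facet(S_[si].v, i, d_);
        fmap[facet_key(f, d_)] = si;
      }
    }

    std::vector<char> conflict(S_.size(), 0);
    int nconf = 0;
    for (int si : alive_idx) {
      const Simplex& s = S_[si];
      bool c = false;
      if (!is_infinite(s)) {
        c = insphere_idx(s.v, ip) > tol_;
      } else {
        c = infinite_conflict(si, fmap, ip, tol_);
      }
      if (c) { conflict[si] = 1; ++nconf; }
    }

    if (nconf == 0) {
      // fallback: point within tolerance of circumballs; locate the simplex
      // whose closure contains it and carve that one
      int best = -1; double bestv = -1e300;
      for (int si : alive_idx) {
        const Simplex& s = S_[si];
        if (is_infinite(s)) continue;
        double v = insphere_idx(s.v, ip);
        if (v > bestv && contains(s.v, ip)) { bestv = v; best = si; }
      }
      if (best < 0) {
        // on/outside hull boundary: take the most-nearly-visible hull facet
        double bv = 1e300; int bi = -1;
        for (int si : alive_idx) {
          if (!is_infinite(S_[si])) continue;
          double v = infinite_visibility(si, fmap, ip);
          if (v < bv) { bv = v; bi = si; }
        }
        if (bi < 0) stop("insertion failed for point %d", ip + 1);
        best = bi;
      }
      conflict[best] = 1; nconf = 1;
    }

    // boundary facets: appear in exactly one conflict simplex
    std::map<Facet, int> count;
    for (int si : alive_idx) {
      if (!conflict[si]) continue;
      for (int i = 0; i <= d_; ++i) count[make_facet(S_[si].v, i, d_)]++;
    }
    std::vector<Simplex> fresh;
    for (std::map<Facet,int>::iterator it = count.begin(); it != count.end(); ++it) {
      if (it->second != 1) continue;
      // shared with a non-conflict simplex, or a hull facet of the cavity
      const Facet& f = it->first;
      Simplex ns; ns.alive = true; ns.v.fill(INT_MAX);
      int k = 0; bool inf = false;
      for (int j = 0; j < d_; ++j) {
        if (f[j] == INF_V) { inf = true; continue; }
        ns.v[k++] = f[j];
      }
      ns.v[k++] = ip;
      if (inf) ns.v[k++] = INF_V;
      if (!inf) {
        double o = orient_of(ns.v);
        if (std::fabs(o) <= tol_)
          stop("degenerate simplex while inserting point %d", ip + 1);
        if (o < 0) std::swap(ns.v[0], ns.v[1]);
      }
      fresh.push_back(ns);
    }
    for (int si : alive_idx) if (conflict[si]) S_[si].alive = false;
    for (size_t i = 0; i < fresh.size(); ++i) S_.push_back(fresh[i]);
  }

  // true strict visibility conflict for an infinite simplex
  bool infinite_conflict(int si, FMap& fmap, int ip, double tol) {
    return infinite_visibility(si, fmap, ip) < -tol;
  }

  // signed visibility: negative if ip on the outer side of the hull facet of
  // infinite simplex si (sign referenced to the inner finite simplex)
  double infinite_visibility(int si, FMap& fmap, int ip) {
    const Simplex& s = S_[si];
    int fv[3]; int k = 0;
    for (int i = 0; i <= d_; ++i) if (s.v[i] != INF_V) fv[k++] = s.v[i];
    Facet f; f.fill(INT_MAX);
    for (int i = 0; i < d_; ++i) f[i] = fv[i];
    std::sort(f.begin(), f.begin() + d_);
    FMap::iterator it = fmap.find(facet_key(f, d_));
    if (it == fmap.end()) stop("internal: hull facet without finite neighbor");
    int sfin = it->second;
    int vop = -2;
    for (int i = 0; i <= d_; ++i) {
      int u = S_[sfin].v[i];
      bool onf = false;
      for (int j = 0; j < d_; ++j) if (fv[j] == u) onf = true;
      if (!onf) { vop = u; break; }
    }
    double o_v = orient_idx(fv, vop);
    double o_p = orient_idx(fv, ip);
    if (o_v == 0) stop("internal: degenerate finite simplex at hull");
    return o_v > 0 ? o_p : -o_p;
  }

  // closure containment test for a finite, positively oriented simplex
  bool contains(const std::array<int,4>& v, int ip) const {
    std::array<int,4> w;
    for (int i = 0; i <= d_; ++i) {
      w = v; w[i] = ip;
      if (orient_of(w) < -tol_) return false;
    }
    return true;
  }
};

// [[Rcpp::export(name = ".cpp_delaunay")]]
List cpp_delaunay(NumericMatrix coords, double tol = 1e-12) {
  int d = coords.ncol();
  if (d != 2 && d != 3) stop("dimension must be 2 or 3");
  Triangulator tr(coords, tol);
  tr.run();
  return tr.result();
}
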