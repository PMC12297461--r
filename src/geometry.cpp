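// Core computational geometry for restricted 3D Voronoi tessellation.
//
// A Voronoi cell is initialised as a bounded convex solid (regular
// dodecahedron by default) centred on its seed and clipped sequentially by
// the perpendicular-bisector half-spaces to other seeds. Polyhedra are
// stored as vertex lists plus ordered face loops; every face remembers the
// plane that generated it (negative ids: faces of the initial solid or of
// extra container planes, non-negative ids: neighbouring seed indices).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

typedef std::array<double, 3> Vec3;

static inline double dot3(const Vec3 &a, const Vec3 &b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline Vec3 cross3(const Vec3 &a, const Vec3 &b) {
  return Vec3{a[1] * b[2] - a[2] * b[1],
              a[2] * b[0] - a[0] * b[2],
              a[0] * b[1] - a[1] * b[0]};
}
static inline Vec3 sub3(const Vec3 &a, const Vec3 &b) {
  return Vec3{a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
static inline double norm3(const Vec3 &a) { return std::sqrt(dot3(a, a)); }

struct Poly {
  std::vector<Vec3> v;                 // vertices
  std::vector<std::vector<int>> f;     // ordered vertex loops
  std::vector<int> src;                // generating plane id per face
  std::vector<Vec3> fn;                // outward unit normal per face
};

// Clip P by half-space n.x <= d (n unit). Returns 0: untouched, 1: clipped,
// 2: emptied. eps is an absolute tolerance on plane distance.
static int clip_poly(Poly &P, const Vec3 &n, double d, int source, double eps) {
  const int nv = (int)P.v.size();
  if (nv == 0) return 2;
  static thread_local std::vector<double> sd;
  sd.resize(nv);
  int npos = 0, nneg = 0;
  for (int i = 0; i < nv; ++i) {
    sd[i] = dot3(n, P.v[i]) - d;
    if (sd[i] > eps) ++npos; else if (sd[i] < -eps) ++nneg;
  }
  if (npos == 0) return 0;
  if (nneg == 0) { P.v.clear(); P.f.clear(); P.src.clear(); P.fn.clear(); return 2; }

  Poly Q;
  Q.v.reserve(nv + 8);
  std::vector<int> remap(nv, -1);
  for (int i = 0; i < nv; ++i)
    if (sd[i] <= eps) { remap[i] = (int)Q.v.size(); Q.v.push_back(P.v[i]); }

  std::map<std::pair<int, int>, int> edge_cache;
  for (size_t fi = 0; fi < P.f.size(); ++fi) {
    const std::vector<int> &loop = P.f[fi];
    std::vector<int> nl;
    const int m = (int)loop.size();
    for (int k = 0; k < m; ++k) {
      const int a = loop[k], b = loop[(k + 1) % m];
      if (sd[a] <= eps) nl.push_back(remap[a]);
      const bool crossing = (sd[a] > eps && sd[b] < -eps) ||
                            (sd[a] < -eps && sd[b] > eps);
      if (crossing) {
        std::pair<int, int> key = std::minmax(a, b);
        std::map<std::pair<int, int>, int>::iterator it = edge_cache.find(key);
        int id;
        if (it != edge_cache.end()) id = it->second;
        else {
          const double t = sd[a] / (sd[a] - sd[b]);
          Vec3 x{P.v[a][0] + t * (P.v[b][0] - P.v[a][0]),
                 P.v[a][1] + t * (P.v[b][1] - P.v[a][1]),
                 P.v[a][2] + t * (P.v[b][2] - P.v[a][2])};
          id = (int)Q.v.size();
          Q.v.push_back(x);
          edge_cache[key] = id;
        }
        nl.push_back(id);
      }
    }
    // drop consecutive duplicates that tolerance classification can produce
    std::vector<int> cl;
    for (size_t k = 0; k < nl.size(); ++k)
      if (cl.empty() || nl[k] != cl.back()) cl.push_back(nl[k]);
    if (cl.size() >= 2 && cl.front() == cl.back()) cl.pop_back();
    if (cl.size() >= 3) {
      Q.f.push_back(cl);
      Q.src.push_back(P.src[fi]);
      Q.fn.push_back(P.fn[fi]);
    }
  }

  // cap face: every surviving vertex lying on the clip plane
  std::vector<int> cap;
  for (size_t i = 0; i < Q.v.size(); ++i)
    if (std::fabs(dot3(n, Q.v[i]) - d) <= 2.0 * eps) cap.push_back((int)i);
  if (cap.size() >= 3) {
    // order by angle in the plane about the cap centroid
    Vec3 c{0, 0, 0};
    for (size_t k = 0; k < cap.size(); ++k)
      for (int j = 0; j < 3; ++j) c[j] += Q.v[cap[k]][j];
    for (int j = 0; j < 3; ++j) c[j] /= (double)cap.size();
    // basis perpendicular to n
    Vec3 ref{1, 0, 0};
    if (std::fabs(n[0]) > 0.9) ref = Vec3{0, 1, 0};
    Vec3 e1 = cross3(n, ref);
    const double e1n = norm3(e1);
    e1 = Vec3{e1[0] / e1n, e1[1] / e1n, e1[2] / e1n};
    Vec3 e2 = cross3(n, e1);
    std::vector<std::pair<double, int>> ang(cap.size());
    for (size_t k = 0; k < cap.size(); ++k) {
      Vec3 r = sub3(Q.v[cap[k]], c);
      ang[k] = std::make_pair(std::atan2(dot3(r, e2), dot3(r, e1)), cap[k]);
    }
    std::sort(ang.begin(), ang.end());
    std::vector<int> loop(cap.size());
    for (size_t k = 0; k < cap.size(); ++k) loop[k] = ang[k].second;
    Q.f.push_back(loop);
    Q.src.push_back(source);
    Q.fn.push_back(n);
  }
  P = Q;
  return 1;
}

// Volume, centroid (about the local origin, assumed interior) and per-face
// areas of a convex polyhedron with outward face normals.
static void measure_poly(const Poly &P, double &vol, Vec3 &cen,
                         std::vector<double> &areas) {
  vol = 0.0;
  cen = Vec3{0, 0, 0};
  areas.assign(P.f.size(), 0.0);
  for (size_t fi = 0; fi < P.f.size(); ++fi) {
    const std::vector<int> &loop = P.f[fi];
    const int m = (int)loop.size();
    // Newell normal for area and winding check
    Vec3 nw{0, 0, 0};
    for (int k = 0; k < m; ++k) {
      const Vec3 &a = P.v[loop[k]], &b = P.v[loop[(k + 1) % m]];
      nw[0] += (a[1] - b[1]) * (a[2] + b[2]);
      nw[1] += (a[2] - b[2]) * (a[0] + b[0]);
      nw[2] += (a[0] - b[0]) * (a[1] + b[1]);
    }
    areas[fi] = 0.5 * norm3(nw);
    const double orient = (dot3(nw, P.fn[fi]) >= 0.0) ? 1.0 : -1.0;
    const Vec3 &v0 = P.v[loop[0]];
    for (int k = 1; k + 1 < m; ++k) {
      const Vec3 &va = P.v[loop[k]], &vb = P.v[loop[k + 1]];
      const double sv = orient * dot3(v0, cross3(va, vb)) / 6.0;
      vol += sv;
      cen[0] += sv * (v0[0] + va[0] + vb[0]) / 4.0;
      cen[1] += sv * (v0[1] + va[1] + vb[1]) / 4.0;
      cen[2] += sv * (v0[2] + va[2] + vb[2]) / 4.0;
    }
  }
  if (vol > 0) { cen[0] /= vol; cen[1] /= vol; cen[2] /= vol; }
}

static Poly poly_from_r(const NumericMatrix &vert, const List &faces,
                        const NumericMatrix &planes) {
  Poly P;
  for (int i = 0; i < vert.nrow(); ++i)
    P.v.push_back(Vec3{vert(i, 0), vert(i, 1), vert(i, 2)});
  for (int fi = 0; fi < faces.size(); ++fi) {
    IntegerVector lv = faces[fi];
    std::vector<int> loop(lv.size());
    for (int k = 0; k < lv.size(); ++k) loop[k] = lv[k] - 1;  // 1-based in R
    P.f.push_back(loop);
    P.src.push_back(-(fi + 1));
    P.fn.push_back(Vec3{planes(fi, 0), planes(fi, 1), planes(fi, 2)});
  }
  return P;
}

// ---------------------------------------------------------------------------
// Uniform grid for fixed-radius neighbour queries
struct Grid {
  double x0[3];
  double h;
  int nb[3];
  std::vector<std::vector<int>> cells;
  const NumericMatrix *pts;

  void build(const NumericMatrix &p, double hh) {
    pts = &p;
    h = hh;
    double lo[3], hi[3];
    for (int j = 0; j < 3; ++j) { lo[j] = R_PosInf; hi[j] = R_NegInf; }
    for (int i = 0; i < p.nrow(); ++i)
      for (int j = 0; j < 3; ++j) {
        if (p(i, j) < lo[j]) lo[j] = p(i, j);
        if (p(i, j) > hi[j]) hi[j] = p(i, j);
      }
    for (int j = 0; j < 3; ++j) {
      x0[j] = lo[j];
      nb[j] = std::max(1, (int)std::floor((hi[j] - lo[j]) / h) + 1);
    }
    cells.assign((size_t)nb[0] * nb[1] * nb[2], std::vector<int>());
    for (int i = 0; i < p.nrow(); ++i) cells[index_of(i)].push_back(i);
  }
  int coord(double x, int j) const {
    int c = (int)std::floor((x - x0[j]) / h);
    if (c < 0) c = 0;
    if (c >= nb[j]) c = nb[j] - 1;
    return c;
  }
  size_t index_of(int i) const {
    const NumericMatrix &p = *pts;
    return ((size_t)coord(p(i, 0), 0) * nb[1] + coord(p(i, 1), 1)) * nb[2] +
           coord(p(i, 2), 2);
  }
  // indices with squared distance to q in (0, r2]; excludes `self`
  void query(const Vec3 &q, double r, int self,
             std::vector<std::pair<double, int>> &out) const {
    out.clear();
    query_ring(q, 0.0, r, self, out);
  }

  // indices with squared distance in (r_lo, r_hi]; grid cells already fully
  // covered by the r_lo ball are skipped, so expanding searches touch each
  // point once.
  void query_ring(const Vec3 &q, double r_lo, double r_hi, int self,
                  std::vector<std::pair<double, int>> &out) const {
    const NumericMatrix &p = *pts;
    const double lo2 = r_lo * r_lo, hi2 = r_hi * r_hi;
    int clo[3], chi[3];
    for (int j = 0; j < 3; ++j) {
      clo[j] = coord(q[j] - r_hi, j);
      chi[j] = coord(q[j] + r_hi, j);
    }
    for (int a = clo[0]; a <= chi[0]; ++a)
      for (int b = clo[1]; b <= chi[1]; ++b)
        for (int c = clo[2]; c <= chi[2]; ++c) {
          if (r_lo > 0) {
            // farthest corner of this grid cell from q
            double m2 = 0.0;
            const double cl[3] = {x0[0] + a * h, x0[1] + b * h, x0[2] + c * h};
            const double cc[3] = {q[0], q[1], q[2]};
            for (int j = 0; j < 3; ++j) {
              const double lo_d = std::fabs(cc[j] - cl[j]);
              const double hi_d = std::fabs(cc[j] - (cl[j] + h));
              const double m = std::max(lo_d, hi_d);
              m2 += m * m;
            }
            if (m2 <= lo2) continue;  // entirely inside the previous ball
          }
          const std::vector<int> &cell =
              cells[((size_t)a * nb[1] + b) * nb[2] + c];
          for (size_t k = 0; k < cell.size(); ++k) {
            const int i = cell[k];
            if (i == self) continue;
            const double dx = p(i, 0) - q[0], dy = p(i, 1) - q[1],
                         dz = p(i, 2) - q[2];
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 > lo2 && d2 <= hi2) out.push_back(std::make_pair(d2, i));
          }
        }
  }
};

// ---------------------------------------------------------------------------
// Restricted Voronoi tessellation.
//
// points:     (n x 3) seeds; cells are computed for the first n_compute rows
//             (the remainder act as clipping neighbours only, e.g. auxiliary
//             points).
// init_*:     bounding solid centred on each seed, in seed-local coordinates
//             (vertices, 1-based face loops, unit outward face normals).
// container:  optional (m x 4) global half-spaces n.x <= d (0-row matrix for
//             none); their faces count as unshared, like the initial solid's.
// [[Rcpp::export]]
List cpp_restricted_voronoi(NumericMatrix points, int n_compute,
                            NumericMatrix init_vert, List init_faces,
                            NumericMatrix init_normals,
                            NumericMatrix container, double area_tol,
                            double eps) {
  const int n = points.nrow();
  Poly init = poly_from_r(init_vert, init_faces, init_normals);
  double circum = 0.0;
  for (size_t i = 0; i < init.v.size(); ++i)
    circum = std::max(circum, norm3(init.v[i]));
  const double rcut = 2.0 * circum * 1.0000001;

  // grid sized to typical spacing, bounded to keep memory sane
  double span = 1.0;
  {
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf},
           hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < 3; ++j) {
        lo[j] = std::min(lo[j], points(i, j));
        hi[j] = std::max(hi[j], points(i, j));
      }
    double vol = 1.0;
    for (int j = 0; j < 3; ++j) vol *= std::max(hi[j] - lo[j], 1e-6);
    span = std::cbrt(vol / std::max(1, n));
  }
  const double h = std::max(span, circum / 64.0);
  Grid grid;
  grid.build(points, h);

  NumericVector vol_out(n_compute);
  NumericMatrix cen_out(n_compute, 3);
  IntegerVector n_unshared(n_compute);
  List nb_out(n_compute);

  std::vector<std::pair<double, int>> cand;
  for (int i = 0; i < n_compute; ++i) {
    const Vec3 p{points(i, 0), points(i, 1), points(i, 2)};
    Poly P = init;
    // container planes in seed-local coordinates
    for (int m = 0; m < container.nrow(); ++m) {
      const Vec3 nn{container(m, 0), container(m, 1), container(m, 2)};
      clip_poly(P, nn, container(m, 3) - dot3(nn, p), -100 - m, eps);
    }
    double maxr2 = 0.0;
    for (size_t k = 0; k < P.v.size(); ++k)
      maxr2 = std::max(maxr2, dot3(P.v[k], P.v[k]));
    // expand the candidate search in rings; candidates in later rings are
    // farther than earlier ones, so the sorted-clip early exit is global
    double r_lo = 0.0, r = std::min(rcut, 4.0 * h);
    bool finished = false;
    while (!finished) {
      cand.clear();
      grid.query_ring(p, r_lo, r, i, cand);
      std::sort(cand.begin(), cand.end());
      for (size_t k = 0; k < cand.size(); ++k) {
        if (cand[k].first > 4.0 * maxr2) { finished = true; break; }
        const int j = cand[k].second;
        Vec3 u{points(j, 0) - p[0], points(j, 1) - p[1], points(j, 2) - p[2]};
        const double un = norm3(u);
        if (un < 1e-12) stop("coincident seed points (indices %d, %d)", i + 1, j + 1);
        const Vec3 nn{u[0] / un, u[1] / un, u[2] / un};
        if (clip_poly(P, nn, 0.5 * un, j, eps) == 1) {
          maxr2 = 0.0;
          for (size_t t = 0; t < P.v.size(); ++t)
            maxr2 = std::max(maxr2, dot3(P.v[t], P.v[t]));
        }
      }
      if (finished || 2.0 * std::sqrt(maxr2) <= r || r >= rcut) finished = true;
      else {
        r_lo = r;
        r = std::min(rcut, 2.0 * r);
      }
    }

    double vol;
    Vec3 cen;
    std::vector<double> areas;
    measure_poly(P, vol, cen, areas);
    vol_out[i] = vol;
    cen_out(i, 0) = p[0] + cen[0];
    cen_out(i, 1) = p[1] + cen[1];
    cen_out(i, 2) = p[2] + cen[2];

    std::vector<int> nbr;
    int nun = 0;
    for (size_t fi = 0; fi < P.f.size(); ++fi) {
      if (areas[fi] < area_tol) continue;
      if (P.src[fi] >= 0) nbr.push_back(P.src[fi] + 1);  // back to 1-based
      else ++nun;
    }
    std::sort(nbr.begin(), nbr.end());
    nbr.erase(std::unique(nbr.begin(), nbr.end()), nbr.end());
    n_unshared[i] = nun;
    nb_out[i] = IntegerVector(nbr.begin(), nbr.end());
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["volume"] = vol_out, _["centroid"] = cen_out,
                      _["neighbours"] = nb_out, _["n_unshared"] = n_unshared);
}

// Clip an axis-aligned cube [-halfwidth, halfwidth]^3 by planes (m x 4 rows:
// unit normal, offset; keep n.x <= d). Returns geometry of the result.
// [[Rcpp::export]]
List cpp_clip_region(NumericMatrix planes, double halfwidth, double area_tol,
                     double eps) {
  Poly P;
  const double w = halfwidth;
  const double sgn[2] = {-1.0, 1.0};
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b)
      for (int c = 0; c < 2; ++c)
        P.v.push_back(Vec3{sgn[a] * w, sgn[b] * w, sgn[c] * w});
  // cube faces (vertex order consistent with outward normals via fn)
  const int faces[6][4] = {{0, 1, 3, 2}, {4, 6, 7, 5}, {0, 4, 5, 1},
                           {2, 3, 7, 6}, {0, 2, 6, 4}, {1, 5, 7, 3}};
  const double fns[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                            {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  for (int fi = 0; fi < 6; ++fi) {
    P.f.push_back(std::vector<int>(faces[fi], faces[fi] + 4));
    P.src.push_back(-(fi + 1));
    P.fn.push_back(Vec3{fns[fi][0], fns[fi][1], fns[fi][2]});
  }
  for (int m = 0; m < planes.nrow(); ++m) {
    const Vec3 nn{planes(m, 0), planes(m, 1), planes(m, 2)};
    clip_poly(P, nn, planes(m, 3), m, eps);
    if (P.v.empty()) break;
  }
  double vol;
  Vec3 cen;
  std::vector<double> areas;
  measure_poly(P, vol, cen, areas);
  NumericMatrix vert(P.v.size(), 3);
  for (size_t i = 0; i < P.v.size(); ++i)
    for (int j = 0; j < 3; ++j) vert(i, j) = P.v[i][j];
  IntegerVector fsrc(P.f.size());
  NumericVector farea(P.f.size());
  for (size_t fi = 0; fi < P.f.size(); ++fi) {
    fsrc[fi] = P.src[fi] >= 0 ? P.src[fi] + 1 : P.src[fi];
    farea[fi] = areas[fi];
  }
  return List::create(_["volume"] = vol,
                      _["centroid"] = NumericVector::create(cen[0], cen[1], cen[2]),
                      _["vertices"] = vert, _["face_plane"] = fsrc,
                      _["face_area"] = farea);
}

// Counts of points (excluding the focal point) in concentric shells
// (radii[k-1], radii[k]] around every point. radii[0] pairs with 0.
// [[Rcpp::export]]
IntegerMatrix cpp_count_shells(NumericMatrix points, NumericVector radii) {
  const int n = points.nrow(), nr = radii.size();
  const double rmax = radii[nr - 1];
  Grid grid;
  grid.build(points, std::max(rmax / 2.0, 1e-6));
  IntegerMatrix counts(n, nr);
  std::vector<std::pair<double, int>> out;
  for (int i = 0; i < n; ++i) {
    const Vec3 q{points(i, 0), points(i, 1), points(i, 2)};
    grid.query(q, rmax, i, out);
    for (size_t k = 0; k < out.size(); ++k) {
      const double d = std::sqrt(out[k].first);
      for (int b = 0; b < nr; ++b)
        if (d <= radii[b] && (b == 0 || d > radii[b - 1])) {
          ++counts(i, b);
          break;
        }
    }
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}

// Pair counts for the pair correlation function. For each bin b the
// reference set is {i : dbound[i] >= edges[b+1]} (minus-sampling erosion).
// same_set = true skips the self pair (A and B identical, row-aligned).
// [[Rcpp::export]]
List cpp_pair_counts(NumericMatrix A, NumericMatrix B, NumericVector dbound,
                     NumericVector edges, bool same_set) {
  const int n = A.nrow(), m = B.nrow(), nb = edges.size() - 1;
  const double rmax = edges[nb];
  Grid grid;
  grid.build(B, std::max(rmax / 2.0, 1e-6));
  NumericVector counts(nb);
  IntegerVector nref(nb);
  for (int b = 0; b < nb; ++b)
    for (int i = 0; i < n; ++i)
      if (dbound[i] >= edges[b + 1]) ++nref[b];
  std::vector<std::pair<double, int>> out;
  for (int i = 0; i < n; ++i) {
    const Vec3 q{A(i, 0), A(i, 1), A(i, 2)};
    grid.query(q, rmax, same_set ? i : -1, out);
    for (size_t k = 0; k < out.size(); ++k) {
      const double d = std::sqrt(out[k].first);
      int b = -1;
      for (int t = 0; t < nb; ++t)
        if (d > edges[t] && d <= edges[t + 1]) { b = t; break; }
      if (b >= 0 && dbound[i] >= edges[b + 1]) counts[b] += 1.0;
    }
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["counts"] = counts, _["n_ref"] = nref);
}

// Nearest seed for every query point: 1-based index and distance.
// [[Rcpp::export]]
List cpp_nearest_seed(NumericMatrix seeds, NumericMatrix queries) {
  const int m = seeds.nrow(), q = queries.nrow();
  IntegerVector idx(q);
  NumericVector dist(q);
  for (int i = 0; i < q; ++i) {
    double best = R_PosInf;
    int bi = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = seeds(j, 0) - queries(i, 0),
                   dy = seeds(j, 1) - queries(i, 1),
                   dz = seeds(j, 2) - queries(i, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = j; }
    }
    idx[i] = bi + 1;
    dist[i] = std::sqrt(best);
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Greedy hard-core thinning (random sequential adsorption): accept each
// proposal in order iff it lies >= hardcore from every previously accepted
// point; stop once `target` points are accepted (target < 0: no cap).
// [[Rcpp::export]]
LogicalVector cpp_hardcore_thin(NumericMatrix pts, double hardcore, int target) {
  const int n = pts.nrow();
  LogicalVector keep(n);
  if (hardcore <= 0) {
    for (int i = 0; i < n; ++i) keep[i] = (target < 0 || i < target);
    return keep;
  }
  Grid grid;
  grid.build(pts, hardcore);
  // grid over all proposals; track accepted subset per cell
  std::vector<std::vector<int>> accepted(grid.cells.size());
  const double h2 = hardcore * hardcore;
  int n_acc = 0;
  for (int i = 0; i < n; ++i) {
    if (target >= 0 && n_acc >= target) break;
    const Vec3 q{pts(i, 0), pts(i, 1), pts(i, 2)};
    bool ok = true;
    int clo[3], chi[3];
    for (int j = 0; j < 3; ++j) {
      clo[j] = grid.coord(q[j] - hardcore, j);
      chi[j] = grid.coord(q[j] + hardcore, j);
    }
    for (int a = clo[0]; a <= chi[0] && ok; ++a)
      for (int b = clo[1]; b <= chi[1] && ok; ++b)
        for (int c = clo[2]; c <= chi[2] && ok; ++c) {
          const std::vector<int> &cell =
              accepted[((size_t)a * grid.nb[1] + b) * grid.nb[2] + c];
          for (size_t k = 0; k < cell.size(); ++k) {
            const int j = cell[k];
            const double dx = pts(j, 0) - q[0], dy = pts(j, 1) - q[1],
                         dz = pts(j, 2) - q[2];
            if (dx * dx + dy * dy + dz * dz < h2) { ok = false; break; }
          }
        }
    if (ok) {
      keep[i] = true;
      accepted[grid.index_of(i)].push_back(i);
      ++n_acc;
    }
  }
  return keep;
}

// Minimum pairwise distance check used by hard-core generators.
// [[Rcpp::export]]
double cpp_min_pair_distance(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 2) return R_PosInf;
  double span = 0.0;
  for (int j = 0; j < 3; ++j) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; ++i) {
      lo = std::min(lo, pts(i, j));
      hi = std::max(hi, pts(i, j));
    }
    span = std::max(span, hi - lo);
  }
  Grid grid;
  grid.build(pts, std::max(span / std::cbrt((double)n) , 1e-6));
  double best = R_PosInf;
  std::vector<std::pair<double, int>> out;
  double r = span / std::cbrt((double)n) * 2.0;
  for (int i = 0; i < n; ++i) {
    const Vec3 q{pts(i, 0), pts(i, 1), pts(i, 2)};
    grid.query(q, r, i, out);
    for (size_t k = 0; k < out.size(); ++k) best = std::min(best, out[k].first);
  }
  if (!R_finite(best)) {
    // sparse cloud: fall back to brute force
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        const double dx = pts(i, 0) - pts(j, 0), dy = pts(i, 1) - pts(j, 1),
                     dz = pts(i, 2) - pts(j, 2);
        best = std::min(best, dx * dx + dy * dy + dz * dz);
      }
  }
  return std::sqrt(best);
}
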