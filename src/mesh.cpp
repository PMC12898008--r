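#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
#include <queue>
#include <utility>
#include <algorithm>
using namespace Rcpp;

// 3D convex hull, Delaunay tetrahedralization (Bowyer-Watson) and
// alpha-style sculpting used for closed-surface reconstruction of the
// dangerous-region boundary point cloud.
//
// Predicates are evaluated on deterministically perturbed copies of the
// input coordinates (index-keyed offsets, ~1e-8 of the cloud diameter) so
// that exactly cospherical configurations -- voxel-center lattices, points
// sampled on a sphere -- resolve consistently. Output geometry always uses
// the original coordinates.

struct P3 { double x, y, z; };

static inline double det3(double a1, double a2, double a3,
                          double b1, double b2, double b3,
                          double c1, double c2, double c3) {
  return a1 * (b2 * c3 - b3 * c2) - a2 * (b1 * c3 - b3 * c1) +
         a3 * (b1 * c2 - b2 * c1);
}

// signed volume x6 of (a,b,c,d); > 0 when d is on the positive side of
// triangle (a,b,c) (right-hand rule)
static inline double orient3d(const P3& a, const P3& b, const P3& c, const P3& d) {
  return det3(b.x - a.x, b.y - a.y, b.z - a.z,
              c.x - a.x, c.y - a.y, c.z - a.z,
              d.x - a.x, d.y - a.y, d.z - a.z);
}

// insphere predicate: for a positively oriented tet (a,b,c,d), returns > 0
// when e lies strictly inside the circumsphere.
static inline double insphere(const P3& a, const P3& b, const P3& c,
                              const P3& d, const P3& e) {
  double ax = a.x - e.x, ay = a.y - e.y, az = a.z - e.z;
  double bx = b.x - e.x, by = b.y - e.y, bz = b.z - e.z;
  double cx = c.x - e.x, cy = c.y - e.y, cz = c.z - e.z;
  double dx = d.x - e.x, dy = d.y - e.y, dz = d.z - e.z;
  double al = ax * ax + ay * ay + az * az;
  double bl = bx * bx + by * by + bz * bz;
  double cl = cx * cx + cy * cy + cz * cz;
  double dl = dx * dx + dy * dy + dz * dz;
  // 4x4 determinant | x y z l | expanded along the last column
  double d1 = det3(bx, by, bz, cx, cy, cz, dx, dy, dz);
  double d2 = det3(ax, ay, az, cx, cy, cz, dx, dy, dz);
  double d3 = det3(ax, ay, az, bx, by, bz, dx, dy, dz);
  double d4 = det3(ax, ay, az, bx, by, bz, cx, cy, cz);
  return al * d1 - bl * d2 + cl * d3 - dl * d4;
}

static double circumradius(const P3& a, const P3& b, const P3& c, const P3& d) {
  // solve 2 (v - a) . x = |v|^2 - |a|^2 for v in {b,c,d}
  double m[3][3] = {
    {b.x - a.x, b.y - a.y, b.z - a.z},
    {c.x - a.x, c.y - a.y, c.z - a.z},
    {d.x - a.x, d.y - a.y, d.z - a.z}};
  double rhs[3] = {
    0.5 * ((b.x * b.x + b.y * b.y + b.z * b.z) - (a.x * a.x + a.y * a.y + a.z * a.z)),
    0.5 * ((c.x * c.x + c.y * c.y + c.z * c.z) - (a.x * a.x + a.y * a.y + a.z * a.z)),
    0.5 * ((d.x * d.x + d.y * d.y + d.z * d.z) - (a.x * a.x + a.y * a.y + a.z * a.z))};
  double det = det3(m[0][0], m[0][1], m[0][2], m[1][0], m[1][1], m[1][2],
                    m[2][0], m[2][1], m[2][2]);
  double scale = std::fabs(m[0][0]) + std::fabs(m[0][1]) + std::fabs(m[0][2]) +
                 std::fabs(m[1][0]) + std::fabs(m[1][1]) + std::fabs(m[1][2]) +
                 std::fabs(m[2][0]) + std::fabs(m[2][1]) + std::fabs(m[2][2]);
  if (std::fabs(det) < 1e-14 * scale * scale * scale + 1e-300)
    return 1e30;  // flat tet: treated as infinitely large circumsphere
  double cx = det3(rhs[0], m[0][1], m[0][2], rhs[1], m[1][1], m[1][2],
                   rhs[2], m[2][1], m[2][2]) / det;
  double cy = det3(m[0][0], rhs[0], m[0][2], m[1][0], rhs[1], m[1][2],
                   m[2][0], rhs[2], m[2][2]) / det;
  double cz = det3(m[0][0], m[0][1], rhs[0], m[1][0], m[1][1], rhs[1],
                   m[2][0], m[2][1], rhs[2]) / det;
  double dx = cx - a.x, dy = cy - a.y, dz = cz - a.z;
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// deterministic pseudo-random offset in [-1, 1] keyed by (index, axis)
static inline double hash_unit(int i, int axis) {
  double s = std::sin((double)(i + 1) * 12.9898 + (double)(axis + 1) * 78.233) *
             43758.5453123;
  return 2.0 * (s - std::floor(s)) - 1.0;
}

static std::vector<P3> perturbed_copy(const NumericMatrix& pts, double& diam) {
  int n = pts.nrow();
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; i++)
    for (int k = 0; k < 3; k++) {
      double v = pts(i, k);
      if (v < lo[k]) lo[k] = v;
      if (v > hi[k]) hi[k] = v;
    }
  double dx = hi[0] - lo[0], dy = hi[1] - lo[1], dz = hi[2] - lo[2];
  diam = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (diam <= 0) diam = 1.0;
  double eps = 1e-8 * diam;
  std::vector<P3> out(n);
  for (int i = 0; i < n; i++) {
    out[i].x = pts(i, 0) + eps * hash_unit(i, 0);
    out[i].y = pts(i, 1) + eps * hash_unit(i, 1);
    out[i].z = pts(i, 2) + eps * hash_unit(i, 2);
  }
  return out;
}

// pick 4 affinely independent points (original coordinates); returns false
// when the input is degenerate (collinear / coplanar)
static bool initial_simplex(const NumericMatrix& pts, double diam, int sel[4]) {
  int n = pts.nrow();
  auto P = [&](int i) { return P3{pts(i, 0), pts(i, 1), pts(i, 2)}; };
  sel[0] = 0;
  // farthest from p0
  double best = -1.0;
  for (int i = 1; i < n; i++) {
    double dx = pts(i, 0) - pts(0, 0), dy = pts(i, 1) - pts(0, 1),
           dz = pts(i, 2) - pts(0, 2);
    double d = dx * dx + dy * dy + dz * dz;
    if (d > best) { best = d; sel[1] = i; }
  }
  if (best <= 1e-24 * diam * diam) return false;
  // farthest from the line
  best = -1.0;
  P3 a = P(sel[0]), b = P(sel[1]);
  for (int i = 0; i < n; i++) {
    double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
    double wx = pts(i, 0) - a.x, wy = pts(i, 1) - a.y, wz = pts(i, 2) - a.z;
    double cx = uy * wz - uz * wy, cy = uz * wx - ux * wz, cz = ux * wy - uy * wx;
    double d = cx * cx + cy * cy + cz * cz;
    if (d > best) { best = d; sel[2] = i; }
  }
  if (best <= 1e-20 * diam * diam * diam * diam) return false;
  // farthest from the plane
  best = -1.0; double bestsgn = 0.0;
  P3 c = P(sel[2]);
  for (int i = 0; i < n; i++) {
    double o = orient3d(a, b, c, P(i));
    if (std::fabs(o) > best) { best = std::fabs(o); bestsgn = o; sel[3] = i; }
  }
  if (best <= 1e-18 * diam * diam * diam) return false;
  if (bestsgn < 0) std::swap(sel[1], sel[2]);  // make orientation positive
  return true;
}

// ------------------------------------------------------------------ hull

// [[Rcpp::export]]
IntegerMatrix cpp_convex_hull(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("degenerate-geometry: need at least 4 points");
  double diam;
  std::vector<P3> pp = perturbed_copy(pts, diam);
  int sel[4];
  if (!initial_simplex(pts, diam, sel))
    stop("degenerate-geometry: points are collinear or coplanar");
  double epsv = 1e-12 * diam * diam * diam;

  struct HFace { int a, b, c; bool alive; };
  std::vector<HFace> faces;
  // positively oriented simplex (s0,s1,s2,s3): outward faces
  int s0 = sel[0], s1 = sel[1], s2 = sel[2], s3 = sel[3];
  if (orient3d(pp[s0], pp[s1], pp[s2], pp[s3]) < 0) std::swap(s1, s2);
  faces.push_back({s0, s2, s1, true});
  faces.push_back({s0, s1, s3, true});
  faces.push_back({s1, s2, s3, true});
  faces.push_back({s0, s3, s2, true});

  std::vector<bool> used(n, false);
  used[s0] = used[s1] = used[s2] = used[s3] = true;
  for (int i = 0; i < n; i++) {
    if (used[i]) continue;
    // visible faces
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); f++) {
      if (!faces[f].alive) continue;
      if (orient3d(pp[faces[f].a], pp[faces[f].b], pp[faces[f].c], pp[i]) > epsv)
        vis.push_back((int)f);
    }
    if (vis.empty()) continue;  // interior point
    // horizon = directed edges of visible faces whose reverse is absent
    std::map<std::pair<int, int>, int> dir;
    for (int f : vis) {
      const HFace& F = faces[f];
      dir[{F.a, F.b}]++; dir[{F.b, F.c}]++; dir[{F.c, F.a}]++;
    }
    for (int f : vis) faces[f].alive = false;
    for (std::map<std::pair<int, int>, int>::iterator it = dir.begin();
         it != dir.end(); ++it) {
      int u = it->first.first, v = it->first.second;
      if (dir.find({v, u}) == dir.end())
        faces.push_back({u, v, i, true});
    }
  }
  int nf = 0;
  for (size_t f = 0; f < faces.size(); f++) if (faces[f].alive) nf++;
  IntegerMatrix out(nf, 3);
  int r = 0;
  for (size_t f = 0; f < faces.size(); f++)
    if (faces[f].alive) {
      out(r, 0) = faces[f].a + 1;
      out(r, 1) = faces[f].b + 1;
      out(r, 2) = faces[f].c + 1;
      r++;
    }
  return out;
}

// -------------------------------------------------------------- delaunay

struct Tet {
  int v[4];
  int nb[4];   // neighbor opposite v[k]; -1 = none
  bool alive;
};

class Delaunay {
public:
  std::vector<P3> pts;   // n input (perturbed) + 4 super vertices
  int n;
  std::vector<Tet> tets;
  int last_alive;

  Delaunay(const std::vector<P3>& p, double diam) : pts(p), n((int)p.size()) {
    // bounding box center
    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < n; i++) { cx += pts[i].x; cy += pts[i].y; cz += pts[i].z; }
    cx /= n; cy /= n; cz /= n;
    double a = 1000.0 * (diam + 1.0);
    pts.push_back({cx + a, cy + a, cz + a});
    pts.push_back({cx + a, cy - a, cz - a});
    pts.push_back({cx - a, cy + a, cz - a});
    pts.push_back({cx - a, cy - a, cz + a});
    int s[4] = {n, n + 1, n + 2, n + 3};
    if (orient3d(pts[s[0]], pts[s[1]], pts[s[2]], pts[s[3]]) < 0)
      std::swap(s[1], s[2]);
    Tet t; t.alive = true;
    for (int k = 0; k < 4; k++) { t.v[k] = s[k]; t.nb[k] = -1; }
    tets.push_back(t);
    last_alive = 0;
  }

  double ort(int a, int b, int c, int d) const {
    return orient3d(pts[a], pts[b], pts[c], pts[d]);
  }

  // locate a tet containing p by orientation walk
  int locate(int p) {
    int cur = last_alive;
    if (cur < 0 || cur >= (int)tets.size() || !tets[cur].alive) {
      cur = -1;
      for (int i = (int)tets.size() - 1; i >= 0; i--)
        if (tets[i].alive) { cur = i; break; }
    }
    int guard = 0, limit = 4 * (int)tets.size() + 64;
    int prev = -1;
    for (;;) {
      if (++guard > limit) break;
      const Tet& t = tets[cur];
      int move = -1;
      double worst = -1e-13;
      for (int k = 0; k < 4; k++) {
        // replace v[k] by p; permutation parity keeps sign meaning
        int a[4] = {t.v[0], t.v[1], t.v[2], t.v[3]};
        a[k] = p;
        double o = orient3d(pts[a[0]], pts[a[1]], pts[a[2]], pts[a[3]]);
        if (o < worst) { worst = o; move = k; }
      }
      if (move < 0) return cur;
      int nxt = t.nb[move];
      if (nxt < 0 || !tets[nxt].alive) return cur;  // shouldn't happen inside super tet
      if (nxt == prev) return cur;  // oscillation across a near-coplanar face
      prev = cur;
      cur = nxt;
    }
    // fallback: best tet by maximal worst-case orientation
    int best = -1;
    double bestScore = R_NegInf;
    for (int i = 0; i < (int)tets.size(); i++) {
      if (!tets[i].alive) continue;
      const Tet& t = tets[i];
      double mino = R_PosInf;
      for (int k = 0; k < 4; k++) {
        int a[4] = {t.v[0], t.v[1], t.v[2], t.v[3]};
        a[k] = p;
        double o = orient3d(pts[a[0]], pts[a[1]], pts[a[2]], pts[a[3]]);
        if (o < mino) mino = o;
      }
      if (mino > bestScore) { bestScore = mino; best = i; }
    }
    if (best < 0) stop("triangulation failure: point location failed");
    return best;
  }

  void insert(int p) {
    int start = locate(p);
    // cavity by BFS over circumsphere tests
    std::vector<int> cavity;
    std::vector<char> inCav(tets.size(), 0);
    std::vector<int> stack;
    stack.push_back(start);
    inCav[start] = 1;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      cavity.push_back(t);
      for (int k = 0; k < 4; k++) {
        int u = tets[t].nb[k];
        if (u < 0 || inCav[u] || !tets[u].alive) continue;
        const Tet& T = tets[u];
        if (insphere(pts[T.v[0]], pts[T.v[1]], pts[T.v[2]], pts[T.v[3]], pts[p]) > 0) {
          inCav[u] = 1;
          stack.push_back(u);
        }
      }
    }
    // boundary faces + star-shape repair: every boundary face must be
    // positively oriented towards p; otherwise grow the cavity
    struct BFace { int a, b, c, outside, outIdx; };
    std::vector<BFace> bfaces;
    for (;;) {
      bfaces.clear();
      bool grew = false;
      for (size_t ci = 0; ci < cavity.size() && !grew; ci++) {
        int t = cavity[ci];
        for (int k = 0; k < 4; k++) {
          int u = tets[t].nb[k];
          if (u >= 0 && inCav[u]) continue;
          int f[3]; int m = 0;
          for (int j = 0; j < 4; j++) if (j != k) f[m++] = tets[t].v[j];
          double o = orient3d(pts[f[0]], pts[f[1]], pts[f[2]], pts[p]);
          if (o < 0) { int tmp = f[1]; f[1] = f[2]; f[2] = tmp; o = -o; }
          if (o <= 1e-300 || o < 1e-13) {
            // degenerate boundary face: absorb the outside tet
            if (u >= 0 && tets[u].alive) {
              inCav[u] = 1;
              cavity.push_back(u);
              grew = true;
              break;
            }
          }
          int outIdx = -1;
          if (u >= 0)
            for (int j = 0; j < 4; j++) if (tets[u].nb[j] == t) outIdx = j;
          bfaces.push_back({f[0], f[1], f[2], u, outIdx});
        }
      }
      if (!grew) break;
    }
    // retriangulate
    for (size_t ci = 0; ci < cavity.size(); ci++) tets[cavity[ci]].alive = false;
    std::map<std::pair<int, int>, std::pair<int, int>> edge2tet;  // edge -> (tet, face idx)
    std::vector<int> created;
    for (size_t bi = 0; bi < bfaces.size(); bi++) {
      const BFace& B = bfaces[bi];
      Tet t;
      t.alive = true;
      t.v[0] = B.a; t.v[1] = B.b; t.v[2] = B.c; t.v[3] = p;
      t.nb[0] = -1; t.nb[1] = -1; t.nb[2] = -1; t.nb[3] = B.outside;
      int id = (int)tets.size();
      tets.push_back(t);
      created.push_back(id);
      if (B.outside >= 0 && B.outIdx >= 0) tets[B.outside].nb[B.outIdx] = id;
      // link across edges of the base face: face opposite v[k] (k<3)
      int base[3] = {B.a, B.b, B.c};
      for (int k = 0; k < 3; k++) {
        int u = base[(k + 1) % 3], v = base[(k + 2) % 3];
        std::pair<int, int> key(std::min(u, v), std::max(u, v));
        std::map<std::pair<int, int>, std::pair<int, int>>::iterator it =
            edge2tet.find(key);
        if (it == edge2tet.end()) {
          edge2tet[key] = std::make_pair(id, k);
        } else {
          tets[id].nb[k] = it->second.first;
          tets[it->second.first].nb[it->second.second] = id;
        }
      }
    }
    last_alive = created.empty() ? last_alive : created.back();
  }
};

// Boissonnat-style sculpting of the interior Delaunay complex: peel
// boundary tetrahedra whose exposed faces have an edge longer than alpha,
// longest first, while keeping the complex a topological ball (watertight
// manifold boundary, connected, no vertex lost). Edge length -- not
// circumradius -- drives the carving because for surface-sampled clouds
// (all points near one isosurface) every circumradius is comparable, while
// faces bridging a concavity are recognizably long.
static void sculpt(const std::vector<P3>& pp, std::vector<Tet>& tets,
                   double alpha) {
  int nt = (int)tets.size();
  std::vector<int> vtx_bnd;     // per-vertex boundary-face count
  std::map<std::pair<int, int>, int> edge_bnd;
  int maxv = 0;
  for (int t = 0; t < nt; t++)
    if (tets[t].alive)
      for (int k = 0; k < 4; k++) maxv = std::max(maxv, tets[t].v[k]);
  vtx_bnd.assign(maxv + 1, 0);

  auto aliveNb = [&](int t, int k) {
    int u = tets[t].nb[k];
    return (u >= 0 && tets[u].alive);
  };
  auto faceVerts = [&](int t, int k, int f[3]) {
    int m = 0;
    for (int j = 0; j < 4; j++) if (j != k) f[m++] = tets[t].v[j];
  };
  auto bumpFace = [&](int t, int k, int delta) {
    int f[3];
    faceVerts(t, k, f);
    for (int j = 0; j < 3; j++) vtx_bnd[f[j]] += delta;
    for (int j = 0; j < 3; j++) {
      int u = f[j], v = f[(j + 1) % 3];
      edge_bnd[{std::min(u, v), std::max(u, v)}] += delta;
    }
  };

  auto edgeLen = [&](int u, int v) {
    double dx = pp[u].x - pp[v].x, dy = pp[u].y - pp[v].y, dz = pp[u].z - pp[v].z;
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  };
  // longest edge among the tet's current boundary faces (non-decreasing
  // over the peeling process: faces only ever become boundary)
  auto maxBndEdge = [&](int t) {
    double mx = 0.0;
    for (int k = 0; k < 4; k++) {
      if (aliveNb(t, k)) continue;
      int f[3];
      faceVerts(t, k, f);
      for (int j = 0; j < 3; j++)
        mx = std::max(mx, edgeLen(f[j], f[(j + 1) % 3]));
    }
    return mx;
  };

  typedef std::pair<double, int> QE;
  std::priority_queue<QE> pq;
  for (int t = 0; t < nt; t++) {
    if (!tets[t].alive) continue;
    bool bnd = false;
    for (int k = 0; k < 4; k++)
      if (!aliveNb(t, k)) { bumpFace(t, k, +1); bnd = true; }
    if (!bnd) continue;
    double e = maxBndEdge(t);
    if (e > alpha) pq.push({e, t});
  }

  while (!pq.empty()) {
    int t = pq.top().second;
    pq.pop();
    if (!tets[t].alive) continue;
    double curEdge = maxBndEdge(t);
    if (curEdge <= alpha) continue;
    // carving must descend: the faces this peel exposes may not be coarser
    // than the ones it removes, otherwise peeling a well-sampled convex
    // surface would cascade along interior chords
    double newEdge = 0.0;
    for (int k = 0; k < 4; k++) {
      if (!aliveNb(t, k)) continue;
      int f[3];
      faceVerts(t, k, f);
      for (int j = 0; j < 3; j++)
        newEdge = std::max(newEdge, edgeLen(f[j], f[(j + 1) % 3]));
    }
    if (newEdge > curEdge * (1.0 + 1e-9)) continue;
    int bidx[4], nb_cnt = 0;
    for (int k = 0; k < 4; k++) if (!aliveNb(t, k)) bidx[nb_cnt++] = k;
    if (nb_cnt == 0 || nb_cnt > 2) continue;
    bool ok = false;
    if (nb_cnt == 1) {
      // opposite vertex must be interior
      ok = (vtx_bnd[tets[t].v[bidx[0]]] == 0);
    } else {
      // edge opposite the shared edge of the two boundary faces must be interior
      int u = tets[t].v[bidx[0]], v = tets[t].v[bidx[1]];
      std::pair<int, int> key(std::min(u, v), std::max(u, v));
      std::map<std::pair<int, int>, int>::iterator it = edge_bnd.find(key);
      ok = (it == edge_bnd.end() || it->second == 0);
    }
    if (!ok) continue;
    // remove
    for (int k = 0; k < 4; k++) {
      if (!aliveNb(t, k)) {
        bumpFace(t, k, -1);          // boundary face disappears
      }
    }
    tets[t].alive = false;
    for (int k = 0; k < 4; k++) {
      int u = tets[t].nb[k];
      if (u >= 0 && tets[u].alive) {
        // the shared face becomes boundary of u
        for (int j = 0; j < 4; j++)
          if (tets[u].nb[j] == t) bumpFace(u, j, +1);
        double e = maxBndEdge(u);
        if (e > alpha) pq.push({e, u});
      }
    }
  }
}

// Delaunay + sculpting surface extraction.
// Returns list(faces = F x 3 (1-based), tets = T x 4 (1-based), alpha).
// [[Rcpp::export]]
List cpp_alpha_complex(NumericMatrix pts, double shrink) {
  int n = pts.nrow();
  if (n < 4) stop("degenerate-geometry: need at least 4 points");
  double diam;
  std::vector<P3> pp = perturbed_copy(pts, diam);
  int sel[4];
  if (!initial_simplex(pts, diam, sel))
    stop("degenerate-geometry: points are collinear or coplanar");

  Delaunay D(pp, diam);
  for (int i = 0; i < n; i++) D.insert(i);

  // drop super tets; the interior complex fills the convex hull
  std::vector<Tet>& tets = D.tets;
  double emax = 0.0;
  for (size_t t = 0; t < tets.size(); t++) {
    if (!tets[t].alive) continue;
    bool super = false;
    for (int k = 0; k < 4; k++) if (tets[t].v[k] >= n) super = true;
    if (super) { tets[t].alive = false; continue; }
    for (int a = 0; a < 4; a++)
      for (int b = a + 1; b < 4; b++) {
        double dx = pp[tets[t].v[a]].x - pp[tets[t].v[b]].x;
        double dy = pp[tets[t].v[a]].y - pp[tets[t].v[b]].y;
        double dz = pp[tets[t].v[a]].z - pp[tets[t].v[b]].z;
        emax = std::max(emax, std::sqrt(dx * dx + dy * dy + dz * dz));
      }
  }

  double alpha = R_PosInf;
  if (shrink > 0) {
    // adaptive tight threshold from the median nearest-neighbour spacing
    int m = std::min(n, 4000);
    int step = std::max(1, n / m);
    std::vector<double> nn;
    for (int i = 0; i < n; i += step) {
      double best = R_PosInf;
      for (int j = 0; j < n; j++) {
        if (j == i) continue;
        double dx = pp[i].x - pp[j].x, dy = pp[i].y - pp[j].y, dz = pp[i].z - pp[j].z;
        double d = dx * dx + dy * dy + dz * dz;
        if (d < best) best = d;
      }
      nn.push_back(std::sqrt(best));
    }
    std::sort(nn.begin(), nn.end());
    double dnn = nn[nn.size() / 2];
    double a1 = std::max(2.0 * dnn, 1e-9 * diam);
    double a0 = std::max(emax * 1.0000001, a1);
    alpha = std::exp((1.0 - shrink) * std::log(a0) + shrink * std::log(a1));
    sculpt(pp, tets, alpha);
  }

  // extract boundary faces, outward oriented (normal away from the opposite
  // vertex of the owning tet)
  std::vector<int> fa, fb, fc;
  int ntet = 0;
  for (size_t t = 0; t < tets.size(); t++) {
    if (!tets[t].alive) continue;
    ntet++;
    for (int k = 0; k < 4; k++) {
      int u = tets[t].nb[k];
      if (u >= 0 && tets[u].alive) continue;
      int f[3]; int m = 0;
      for (int j = 0; j < 4; j++) if (j != k) f[m++] = tets[t].v[j];
      int w = tets[t].v[k];
      if (orient3d(pp[f[0]], pp[f[1]], pp[f[2]], pp[w]) > 0)
        std::swap(f[1], f[2]);
      fa.push_back(f[0] + 1); fb.push_back(f[1] + 1); fc.push_back(f[2] + 1);
    }
  }
  IntegerMatrix faces((int)fa.size(), 3);
  for (int i = 0; i < (int)fa.size(); i++) {
    faces(i, 0) = fa[i]; faces(i, 1) = fb[i]; faces(i, 2) = fc[i];
  }
  IntegerMatrix tm(ntet, 4);
  int r = 0;
  for (size_t t = 0; t < tets.size(); t++) {
    if (!tets[t].alive) continue;
    for (int k = 0; k < 4; k++) tm(r, k) = tets[t].v[k] + 1;
    r++;
  }
  return List::create(_["faces"] = faces, _["tets"] = tm, _["alpha"] = alpha);
}
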