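// Physics core for the deformable-cell vertex model.
//
// All per-step work (cortical elastic forces, volume conservation, adhesion
// bonds, vertex-triangle collision handling, plane confinement, damped
// Verlet integration) lives here; R owns scene construction, schedules and
// measurement. Randomness (bond attach/break draws) goes through R's RNG so
// set.seed() in R fully determines a run.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <string>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 v3(double x, double y, double z) { return Vec3{x, y, z}; }
inline Vec3 operator+(Vec3 a, Vec3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline Vec3 operator-(Vec3 a, Vec3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 operator*(double s, Vec3 a) { return v3(s * a.x, s * a.y, s * a.z); }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(Vec3 a, Vec3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }

// Closest point on triangle abc to p (Ericson, Real-Time Collision
// Detection); also returns barycentric coordinates (u, v, w) of the result.
Vec3 closest_point_triangle(Vec3 p, Vec3 a, Vec3 b, Vec3 c,
                            double &u, double &v, double &w) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { u = 1; v = 0; w = 0; return a; }

  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { u = 0; v = 1; w = 0; return b; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double t = d1 / (d1 - d3);
    u = 1 - t; v = t; w = 0;
    return a + t * ab;
  }

  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { u = 0; v = 0; w = 1; return c; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double t = d2 / (d2 - d6);
    u = 1 - t; v = 0; w = t;
    return a + t * ac;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    u = 0; v = 1 - t; w = t;
    return b + t * (c - b);
  }

  double denom = 1.0 / (va + vb + vc);
  double vv = vb * denom, ww = vc * denom;
  u = 1 - vv - ww; v = vv; w = ww;
  return a + vv * ab + ww * ac;
}

struct Contact {
  int vertex;     // global intruding vertex
  int cell;       // violated cell
  int face;       // global face index of violated cell
  double depth;   // perpendicular penetration depth
  double w[3];    // barycentric weights of the foot point
};

class Sim {
public:
  int N = 0, M = 0, Fn = 0, ncell = 0;
  std::vector<Vec3> pos, prev, force;
  std::vector<int> cell_start, cell_nv;   // per cell
  std::vector<int> e0, e1, edge_cell;     // edges (global vertex ids)
  std::vector<double> ek, elrest, el0;
  std::vector<int> f0, f1, f2, face_cell; // faces (global vertex ids)
  std::vector<double> V0, Vcur;
  std::vector<Vec3> fnormal;              // unit face normals
  std::vector<double> farea;
  std::vector<Vec3> vnormal;              // unit outward vertex normals
  std::vector<Vec3> varea;                // accumulated face area vectors
  int volume_weighting = 1;               // 0 uniform magnitude, 1 area-weighted
  std::vector<int> face_ptr;              // faces grouped per cell: [ptr[c], ptr[c+1])
  std::vector<int> face_ord;
  // per-face AABB (refreshed with geometry)
  std::vector<double> fmin[3], fmax[3];
  // per-cell AABB
  std::vector<double> cmin[3], cmax[3];
  // adhesion
  std::vector<int> adhesive;      // 0/1 per vertex
  std::vector<int> partner;       // global vertex id or -1
  double kadh = 0, linlength = 1, connect_length = 0;
  double adh_chance = 0, break_chance = 0;
  // collision, confinement
  double kcol = 0, margin = 0;
  std::vector<Vec3> plane_p, plane_n;
  std::vector<double> plane_k;
  // integrator
  double dt = 0.05, damp = 0.2, mass = 1.0;
  double fet = 1.0, kv = 0.0;
  // events
  std::vector<int> ev_type;                 // 0 constriction, 1 stiffness
  std::vector<double> ev_start, ev_ramp, ev_value;
  std::vector<int> ev_ptr, ev_edges;
  std::vector<std::vector<double>> ev_k0;   // stiffness start values
  std::vector<char> ev_captured;

  std::string abort_reason;

  void load(const List &pack) {
    NumericMatrix P = pack["pos"], Q = pack["prev"];
    N = P.nrow();
    pos.resize(N); prev.resize(N); force.assign(N, v3(0, 0, 0));
    for (int i = 0; i < N; ++i) {
      pos[i] = v3(P(i, 0), P(i, 1), P(i, 2));
      prev[i] = v3(Q(i, 0), Q(i, 1), Q(i, 2));
    }
    IntegerVector cs = pack["cell_start"], cn = pack["cell_nv"];
    ncell = cs.size();
    cell_start.assign(cs.begin(), cs.end());
    cell_nv.assign(cn.begin(), cn.end());

    IntegerMatrix E = pack["edges"];
    M = E.nrow();
    e0.resize(M); e1.resize(M);
    for (int e = 0; e < M; ++e) { e0[e] = E(e, 0); e1[e] = E(e, 1); }
    NumericVector k_ = pack["edge_k"], lr = pack["edge_lrest"], l0_ = pack["edge_l0"];
    ek.assign(k_.begin(), k_.end());
    elrest.assign(lr.begin(), lr.end());
    el0.assign(l0_.begin(), l0_.end());

    IntegerMatrix Fc = pack["faces"];
    Fn = Fc.nrow();
    f0.resize(Fn); f1.resize(Fn); f2.resize(Fn);
    for (int f = 0; f < Fn; ++f) { f0[f] = Fc(f, 0); f1[f] = Fc(f, 1); f2[f] = Fc(f, 2); }
    IntegerVector fcell = pack["face_cell"];
    face_cell.assign(fcell.begin(), fcell.end());
    // group faces by cell
    face_ptr.assign(ncell + 1, 0);
    for (int f = 0; f < Fn; ++f) face_ptr[face_cell[f] + 1]++;
    for (int c = 0; c < ncell; ++c) face_ptr[c + 1] += face_ptr[c];
    face_ord.resize(Fn);
    std::vector<int> cur(face_ptr.begin(), face_ptr.end() - 1);
    for (int f = 0; f < Fn; ++f) face_ord[cur[face_cell[f]]++] = f;

    NumericVector v0 = pack["V0"];
    V0.assign(v0.begin(), v0.end());
    Vcur.assign(ncell, 0.0);

    IntegerVector adh = pack["adhesive"], par = pack["bond_partner"];
    adhesive.assign(adh.begin(), adh.end());
    partner.assign(par.begin(), par.end());

    List ap = pack["params"];
    kadh = as<double>(ap["k_adh"]);
    linlength = as<double>(ap["lin_length"]);
    connect_length = as<double>(ap["connect_length"]);
    adh_chance = as<double>(ap["adhesion_chance"]);
    break_chance = as<double>(ap["break_chance"]);
    kcol = as<double>(ap["k_col"]);
    margin = as<double>(ap["aabb_margin"]);
    dt = as<double>(ap["dt"]);
    damp = as<double>(ap["damping"]);
    mass = as<double>(ap["mass"]);
    fet = as<double>(ap["f_et"]);
    kv = as<double>(ap["k_v"]);
    std::string vw = as<std::string>(ap["volume_weighting"]);
    volume_weighting = (vw == "uniform") ? 0 : 1;
    if (margin < connect_length) margin = connect_length;

    NumericMatrix pp = pack["plane_point"], pn = pack["plane_normal"];
    NumericVector pk = pack["plane_k"];
    for (int i = 0; i < pp.nrow(); ++i) {
      plane_p.push_back(v3(pp(i, 0), pp(i, 1), pp(i, 2)));
      Vec3 n = v3(pn(i, 0), pn(i, 1), pn(i, 2));
      double nn = norm(n);
      plane_n.push_back((1.0 / nn) * n);
      plane_k.push_back(pk[i]);
    }

    IntegerVector et = pack["ev_type"], eptr = pack["ev_ptr"], eed = pack["ev_edges"];
    NumericVector es = pack["ev_start"], er = pack["ev_ramp"], evv = pack["ev_value"];
    ev_type.assign(et.begin(), et.end());
    ev_start.assign(es.begin(), es.end());
    ev_ramp.assign(er.begin(), er.end());
    ev_value.assign(evv.begin(), evv.end());
    ev_ptr.assign(eptr.begin(), eptr.end());
    ev_edges.assign(eed.begin(), eed.end());
    ev_k0.resize(ev_type.size());
    ev_captured.assign(ev_type.size(), 0);

    for (int d = 0; d < 3; ++d) {
      fmin[d].resize(Fn); fmax[d].resize(Fn);
      cmin[d].resize(ncell); cmax[d].resize(ncell);
    }
    fnormal.resize(Fn);
    farea.resize(Fn);
    vnormal.resize(N);
    varea.resize(N);
  }

  // Scheduled changes: baseline cortical strain l0 = f_et * l_rest for every
  // edge, then events overwrite in the order supplied (R sorts by start time
  // so the latest-started event wins on shared edges).
  void apply_events(double t) {
    for (int e = 0; e < M; ++e) el0[e] = fet * elrest[e];
    for (size_t iv = 0; iv < ev_type.size(); ++iv) {
      if (t < ev_start[iv]) continue;
      double frac = ev_ramp[iv] > 0 ?
        std::min(1.0, (t - ev_start[iv]) / ev_ramp[iv]) : 1.0;
      if (ev_type[iv] == 0) {           // constriction: l0 multiplier ramps 1 -> f_c
        double mult = 1.0 + frac * (ev_value[iv] - 1.0);
        for (int j = ev_ptr[iv]; j < ev_ptr[iv + 1]; ++j) {
          int e = ev_edges[j];
          el0[e] = mult * fet * elrest[e];
        }
      } else {                          // stiffness: k ramps from value at start
        if (!ev_captured[iv]) {
          ev_k0[iv].resize(ev_ptr[iv + 1] - ev_ptr[iv]);
          for (int j = ev_ptr[iv]; j < ev_ptr[iv + 1]; ++j)
            ev_k0[iv][j - ev_ptr[iv]] = ek[ev_edges[j]];
          ev_captured[iv] = 1;
        }
        for (int j = ev_ptr[iv]; j < ev_ptr[iv + 1]; ++j) {
          double k0 = ev_k0[iv][j - ev_ptr[iv]];
          ek[ev_edges[j]] = k0 + frac * (ev_value[iv] - k0);
        }
      }
    }
  }

  // Face normals/areas, per-cell signed volumes, outward vertex normals,
  // per-face and per-cell AABBs.
  bool geometry() {
    std::fill(vnormal.begin(), vnormal.end(), v3(0, 0, 0));
    std::fill(Vcur.begin(), Vcur.end(), 0.0);
    for (int f = 0; f < Fn; ++f) {
      Vec3 a = pos[f0[f]], b = pos[f1[f]], c = pos[f2[f]];
      Vec3 n = cross(b - a, c - a);          // |n| = 2A, outward for stored winding
      double nn = norm(n);
      farea[f] = 0.5 * nn;
      fnormal[f] = nn > 0 ? (1.0 / nn) * n : v3(0, 0, 0);
      Vcur[face_cell[f]] += dot(a, n) / 6.0; // divergence-theorem volume
      vnormal[f0[f]] = vnormal[f0[f]] + n;   // area-weighted accumulation
      vnormal[f1[f]] = vnormal[f1[f]] + n;
      vnormal[f2[f]] = vnormal[f2[f]] + n;
      fmin[0][f] = std::min(a.x, std::min(b.x, c.x));
      fmin[1][f] = std::min(a.y, std::min(b.y, c.y));
      fmin[2][f] = std::min(a.z, std::min(b.z, c.z));
      fmax[0][f] = std::max(a.x, std::max(b.x, c.x));
      fmax[1][f] = std::max(a.y, std::max(b.y, c.y));
      fmax[2][f] = std::max(a.z, std::max(b.z, c.z));
    }
    for (int i = 0; i < N; ++i) {
      varea[i] = 0.5 * vnormal[i];   // sum of adjacent face area vectors
      double nn = norm(vnormal[i]);
      if (nn > 0) vnormal[i] = (1.0 / nn) * vnormal[i];
    }
    for (int c = 0; c < ncell; ++c) {
      if (!(Vcur[c] > 0.0)) {
        abort_reason = "mesh inversion: cell " + std::to_string(c + 1) +
          " has non-positive volume";
        return false;
      }
      double mn[3] = {std::numeric_limits<double>::infinity(),
                      std::numeric_limits<double>::infinity(),
                      std::numeric_limits<double>::infinity()};
      double mx[3] = {-mn[0], -mn[1], -mn[2]};
      for (int i = cell_start[c]; i < cell_start[c] + cell_nv[c]; ++i) {
        mn[0] = std::min(mn[0], pos[i].x); mx[0] = std::max(mx[0], pos[i].x);
        mn[1] = std::min(mn[1], pos[i].y); mx[1] = std::max(mx[1], pos[i].y);
        mn[2] = std::min(mn[2], pos[i].z); mx[2] = std::max(mx[2], pos[i].z);
      }
      for (int d = 0; d < 3; ++d) { cmin[d][c] = mn[d]; cmax[d][c] = mx[d]; }
    }
    return true;
  }

  // Candidate cell pairs whose margin-inflated AABBs overlap.
  std::vector<std::pair<int, int>> broad_phase() const {
    std::vector<std::pair<int, int>> pairs;
    for (int a = 0; a < ncell; ++a)
      for (int b = a + 1; b < ncell; ++b) {
        bool ok = true;
        for (int d = 0; d < 3 && ok; ++d)
          if (cmin[d][a] - margin > cmax[d][b] + margin ||
              cmin[d][b] - margin > cmax[d][a] + margin) ok = false;
        if (ok) pairs.push_back({a, b});
      }
    return pairs;
  }

  void elastic_forces() {
    for (int e = 0; e < M; ++e) {
      Vec3 d = pos[e1[e]] - pos[e0[e]];
      double l = norm(d);
      if (l <= 0) continue;
      double x = l - el0[e];
      if (x < -el0[e]) continue;   // softening clamp: the response crosses zero at x = -l0
      double F = -(ek[e] / el0[e]) * x * x - ek[e] * x;
      Vec3 u = (1.0 / l) * d;
      force[e1[e]] = force[e1[e]] + F * u;
      force[e0[e]] = force[e0[e]] - F * u;
    }
  }

  // Volume restoring force, magnitude k_v |V - V0| / V0 along the outward
  // vertex normal (inward when over volume). The default "area" weighting
  // scales each vertex by its share of the surface area vector, which makes
  // the forces of a closed cell sum to exactly zero (a pressure force);
  // "uniform" applies the same magnitude to every vertex.
  void volume_forces() {
    if (kv <= 0) return;
    for (int c = 0; c < ncell; ++c) {
      double s = (Vcur[c] - V0[c]) / V0[c];
      if (s == 0) continue;
      double mag = -kv * s;   // > 0 (outward) when V < V0
      if (volume_weighting == 0) {
        for (int i = cell_start[c]; i < cell_start[c] + cell_nv[c]; ++i)
          force[i] = force[i] + mag * vnormal[i];
      } else {
        double abar = 0;
        for (int i = cell_start[c]; i < cell_start[c] + cell_nv[c]; ++i)
          abar += norm(varea[i]);
        abar /= cell_nv[c];
        if (abar <= 0) continue;
        double f = mag / abar;
        for (int i = cell_start[c]; i < cell_start[c] + cell_nv[c]; ++i)
          force[i] = force[i] + f * varea[i];
      }
    }
  }

  void adhesion_forces() {
    for (int i = 0; i < N; ++i) {
      int j = partner[i];
      if (j <= i) continue;
      Vec3 d = pos[j] - pos[i];
      double l = norm(d);
      if (l <= 0) continue;
      double mag = l <= linlength ? kadh * l / linlength : kadh;
      Vec3 u = (mag / l) * d;
      force[i] = force[i] + u;
      force[j] = force[j] - u;
    }
  }

  void plane_forces() {
    for (size_t p = 0; p < plane_p.size(); ++p) {
      for (int i = 0; i < N; ++i) {
        double d = dot(pos[i] - plane_p[p], plane_n[p]);
        if (d < 0) force[i] = force[i] + (-d * plane_k[p]) * plane_n[p];
      }
    }
  }

  int cell_of_vertex(int v) const {
    // cells are contiguous vertex ranges; binary search
    int lo = 0, hi = ncell - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (cell_start[mid] <= v) lo = mid; else hi = mid - 1;
    }
    return lo;
  }

  // Stochastic bond turnover. Existing bonds break with break_chance %, then
  // for each candidate pair every unbonded adhesive vertex tries to bond its
  // nearest unbonded adhesive partner in range with adhesion_chance %.
  // Iteration order is fixed (ascending ids) so runs are reproducible.
  void update_bonds(const std::vector<std::pair<int, int>> &pairs) {
    if (break_chance > 0) {
      for (int i = 0; i < N; ++i) {
        int j = partner[i];
        if (j > i && R::unif_rand() * 100.0 < break_chance) {
          partner[i] = -1; partner[j] = -1;
        }
      }
    }
    if (adh_chance <= 0) return;
    for (const auto &pr : pairs) {
      bond_pass(pr.first, pr.second);
      bond_pass(pr.second, pr.first);
    }
  }

  void bond_pass(int a, int b) {
    // overlap box of the two inflated AABBs, guaranteed to contain every
    // vertex within connect_length of the other cell
    double omin[3], omax[3];
    for (int d = 0; d < 3; ++d) {
      omin[d] = std::max(cmin[d][a], cmin[d][b]) - margin;
      omax[d] = std::min(cmax[d][a], cmax[d][b]) + margin;
    }
    std::vector<int> cand_b;
    for (int j = cell_start[b]; j < cell_start[b] + cell_nv[b]; ++j) {
      if (!adhesive[j] || partner[j] >= 0) continue;
      if (pos[j].x < omin[0] || pos[j].x > omax[0] ||
          pos[j].y < omin[1] || pos[j].y > omax[1] ||
          pos[j].z < omin[2] || pos[j].z > omax[2]) continue;
      cand_b.push_back(j);
    }
    if (cand_b.empty()) return;
    double c2 = connect_length * connect_length;
    for (int i = cell_start[a]; i < cell_start[a] + cell_nv[a]; ++i) {
      if (!adhesive[i] || partner[i] >= 0) continue;
      if (pos[i].x < omin[0] || pos[i].x > omax[0] ||
          pos[i].y < omin[1] || pos[i].y > omax[1] ||
          pos[i].z < omin[2] || pos[i].z > omax[2]) continue;
      int best = -1;
      double bestd = c2;
      for (int j : cand_b) {
        if (partner[j] >= 0) continue;
        Vec3 d = pos[j] - pos[i];
        double dd = dot(d, d);
        if (dd < bestd || (dd == bestd && (best < 0 || j < best))) {
          bestd = dd; best = j;
        }
      }
      if (best >= 0 && R::unif_rand() * 100.0 < adh_chance) {
        partner[i] = best; partner[best] = i;
      }
    }
  }

  // Narrow phase for one ordered pair: vertices of cell a against faces of
  // cell b. A vertex is inside when its nearest-feature signed distance is
  // negative (outward face normals). Only vertices inside b's raw AABB can
  // be inside b, so the prefilter loses no true contact.
  void find_contacts_dir(int a, int b, std::vector<Contact> &out) const {
    for (int i = cell_start[a]; i < cell_start[a] + cell_nv[a]; ++i) {
      Vec3 p = pos[i];
      if (p.x < cmin[0][b] || p.x > cmax[0][b] ||
          p.y < cmin[1][b] || p.y > cmax[1][b] ||
          p.z < cmin[2][b] || p.z > cmax[2][b]) continue;
      double best = std::numeric_limits<double>::infinity();
      int bestf = -1;
      double bw[3] = {0, 0, 0};
      Vec3 bestcp = v3(0, 0, 0);
      for (int fi = face_ptr[b]; fi < face_ptr[b + 1]; ++fi) {
        int f = face_ord[fi];
        if (farea[f] <= 0) continue;          // degenerate face skipped
        // cheap reject: squared distance to the face AABB
        double dd = 0;
        double c0 = std::max(fmin[0][f] - p.x, std::max(0.0, p.x - fmax[0][f]));
        double c1 = std::max(fmin[1][f] - p.y, std::max(0.0, p.y - fmax[1][f]));
        double c2_ = std::max(fmin[2][f] - p.z, std::max(0.0, p.z - fmax[2][f]));
        dd = c0 * c0 + c1 * c1 + c2_ * c2_;
        if (dd >= best) continue;
        double u, v, w;
        Vec3 cp = closest_point_triangle(p, pos[f0[f]], pos[f1[f]], pos[f2[f]], u, v, w);
        Vec3 dvec = p - cp;
        double d2 = dot(dvec, dvec);
        if (d2 < best) {
          best = d2; bestf = f; bestcp = cp;
          bw[0] = u; bw[1] = v; bw[2] = w;
        }
      }
      if (bestf < 0) continue;
      double s = dot(p - bestcp, fnormal[bestf]);
      if (s < 0) {
        Contact c;
        c.vertex = i; c.cell = b; c.face = bestf;
        c.depth = std::sqrt(best);
        c.w[0] = bw[0]; c.w[1] = bw[1]; c.w[2] = bw[2];
        out.push_back(c);
      }
    }
  }

  std::vector<Contact> find_contacts(const std::vector<std::pair<int, int>> &pairs) const {
    std::vector<Contact> out;
    for (const auto &pr : pairs) {
      find_contacts_dir(pr.first, pr.second, out);
      find_contacts_dir(pr.second, pr.first, out);
    }
    return out;
  }

  // Restorative force k_col * depth: intruding vertex pushed along the
  // face's outward normal, the opposite force distributed over the three
  // face corners by the foot point's barycentric weights (net force zero).
  void collision_forces(const std::vector<Contact> &contacts) {
    for (const Contact &c : contacts) {
      double mag = kcol * c.depth;
      Vec3 f = mag * fnormal[c.face];
      force[c.vertex] = force[c.vertex] + f;
      force[f0[c.face]] = force[f0[c.face]] - c.w[0] * f;
      force[f1[c.face]] = force[f1[c.face]] - c.w[1] * f;
      force[f2[c.face]] = force[f2[c.face]] - c.w[2] * f;
    }
  }

  bool forces_finite() const {
    for (int i = 0; i < N; ++i)
      if (!std::isfinite(force[i].x) || !std::isfinite(force[i].y) ||
          !std::isfinite(force[i].z)) return false;
    return true;
  }

  // Identify which force module produced a non-finite value (failure path).
  std::string diagnose_forces(const std::vector<std::pair<int, int>> &pairs) {
    const char *names[] = {"elastic", "volume", "adhesion", "collision", "confinement"};
    for (int m = 0; m < 5; ++m) {
      std::fill(force.begin(), force.end(), v3(0, 0, 0));
      switch (m) {
        case 0: elastic_forces(); break;
        case 1: volume_forces(); break;
        case 2: adhesion_forces(); break;
        case 3: collision_forces(find_contacts(pairs)); break;
        case 4: plane_forces(); break;
      }
      if (!forces_finite()) return names[m];
    }
    return "unknown";
  }

  void integrate() {
    double a_fac = dt * dt / mass;
    for (int i = 0; i < N; ++i) {
      Vec3 xn = pos[i];
      Vec3 xnew = (2.0 - damp) * xn - (1.0 - damp) * prev[i] + a_fac * force[i];
      prev[i] = xn;
      pos[i] = xnew;
    }
  }

  NumericMatrix pos_matrix() const {
    NumericMatrix out(N, 3);
    for (int i = 0; i < N; ++i) {
      out(i, 0) = pos[i].x; out(i, 1) = pos[i].y; out(i, 2) = pos[i].z;
    }
    return out;
  }
};

} // namespace

// [[Rcpp::export]]
List simulate_core(List pack, double t0, int nsteps, int record_stride,
                   int bond_stride, int collision_stride) {
  Sim sim;
  sim.load(pack);

  std::vector<double> rec_t;
  std::vector<NumericMatrix> rec_pos;
  std::vector<std::vector<double>> rec_vol;
  std::vector<int> rec_bonds;
  std::vector<double> rec_kin;

  bool ok = true;
  std::string reason;
  double t = t0;
  int done = 0;

  for (int step = 0; step < nsteps; ++step) {
    t = t0 + step * sim.dt;
    sim.apply_events(t);
    if (!sim.geometry()) { ok = false; reason = sim.abort_reason; break; }
    auto pairs = sim.broad_phase();
    if (bond_stride > 0 && step % bond_stride == 0) sim.update_bonds(pairs);

    std::fill(sim.force.begin(), sim.force.end(), v3(0, 0, 0));
    sim.elastic_forces();
    sim.volume_forces();
    sim.adhesion_forces();
    if (collision_stride > 0 && step % collision_stride == 0)
      sim.collision_forces(sim.find_contacts(pairs));
    sim.plane_forces();
    if (!sim.forces_finite()) {
      ok = false;
      reason = "non-finite force from module: " + sim.diagnose_forces(pairs);
      break;
    }
    sim.integrate();
    ++done;

    if ((record_stride > 0 && (step + 1) % record_stride == 0) ||
        step == nsteps - 1) {
      if (!sim.geometry()) { ok = false; reason = sim.abort_reason; break; }
      rec_t.push_back(t0 + (step + 1) * sim.dt);
      rec_pos.push_back(sim.pos_matrix());
      rec_vol.push_back(sim.Vcur);
      int nb = 0;
      for (int i = 0; i < sim.N; ++i) if (sim.partner[i] > i) ++nb;
      rec_bonds.push_back(nb);
      double kin = 0;
      for (int i = 0; i < sim.N; ++i) {
        Vec3 d = sim.pos[i] - sim.prev[i];
        kin += dot(d, d);
      }
      rec_kin.push_back(kin);
    }
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix volmat(rec_vol.size(), sim.ncell);
  for (size_t r = 0; r < rec_vol.size(); ++r)
    for (int c = 0; c < sim.ncell; ++c) volmat(r, c) = rec_vol[r][c];

  List rp(rec_pos.size());
  for (size_t r = 0; r < rec_pos.size(); ++r) rp[r] = rec_pos[r];

  NumericMatrix prevmat(sim.N, 3);
  for (int i = 0; i < sim.N; ++i) {
    prevmat(i, 0) = sim.prev[i].x; prevmat(i, 1) = sim.prev[i].y;
    prevmat(i, 2) = sim.prev[i].z;
  }

  return List::create(
    _["ok"] = ok,
    _["abort_reason"] = reason,
    _["steps_done"] = done,
    _["t"] = t0 + done * sim.dt,
    _["pos"] = sim.pos_matrix(),
    _["prev"] = prevmat,
    _["edge_l0"] = NumericVector(sim.el0.begin(), sim.el0.end()),
    _["edge_k"] = NumericVector(sim.ek.begin(), sim.ek.end()),
    _["bond_partner"] = IntegerVector(sim.partner.begin(), sim.partner.end()),
    _["rec_time"] = NumericVector(rec_t.begin(), rec_t.end()),
    _["rec_pos"] = rp,
    _["rec_volume"] = volmat,
    _["rec_bonds"] = IntegerVector(rec_bonds.begin(), rec_bonds.end()),
    _["rec_kinetic"] = NumericVector(rec_kin.begin(), rec_kin.end()));
}

// One force evaluation at time t, split by module (no bond turnover, no
// integration). Used to interrogate force balance in tests and diagnostics.
// [[Rcpp::export]]
List forces_core(List pack, double t) {
  Sim sim;
  sim.load(pack);
  sim.apply_events(t);
  if (!sim.geometry()) stop(sim.abort_reason);
  auto pairs = sim.broad_phase();

  NumericMatrix total(sim.N, 3);
  List comps;
  const char *names[] = {"elastic", "volume", "adhesion", "collision", "confinement"};
  for (int m = 0; m < 5; ++m) {
    std::fill(sim.force.begin(), sim.force.end(), v3(0, 0, 0));
    switch (m) {
      case 0: sim.elastic_forces(); break;
      case 1: sim.volume_forces(); break;
      case 2: sim.adhesion_forces(); break;
      case 3: sim.collision_forces(sim.find_contacts(pairs)); break;
      case 4: sim.plane_forces(); break;
    }
    NumericMatrix comp(sim.N, 3);
    for (int i = 0; i < sim.N; ++i) {
      comp(i, 0) = sim.force[i].x; comp(i, 1) = sim.force[i].y;
      comp(i, 2) = sim.force[i].z;
      total(i, 0) += comp(i, 0); total(i, 1) += comp(i, 1); total(i, 2) += comp(i, 2);
    }
    comps.push_back(comp, names[m]);
  }
  comps.push_back(total, "total");
  return comps;
}

// Broad + narrow phase contact detection on the current positions.
// Returns one row per vertex-through-face penetration.
// [[Rcpp::export]]
DataFrame contacts_core(List pack) {
  Sim sim;
  sim.load(pack);
  if (!sim.geometry()) stop(sim.abort_reason);
  auto pairs = sim.broad_phase();
  auto contacts = sim.find_contacts(pairs);

  int n = contacts.size();
  IntegerVector cellA(n), vertexA(n), cellB(n), faceB(n);
  NumericVector depth(n), w1(n), w2(n), w3(n);
  for (int i = 0; i < n; ++i) {
    const Contact &c = contacts[i];
    int ca = sim.cell_of_vertex(c.vertex);
    cellA[i] = ca + 1;
    vertexA[i] = c.vertex - sim.cell_start[ca] + 1;
    cellB[i] = c.cell + 1;
    faceB[i] = c.face - sim.face_ptr[c.cell] + 1;
    depth[i] = c.depth;
    w1[i] = c.w[0]; w2[i] = c.w[1]; w3[i] = c.w[2];
  }
  return DataFrame::create(
    _["cell"] = cellA, _["vertex"] = vertexA,
    _["violated_cell"] = cellB, _["face"] = faceB,
    _["depth"] = depth, _["w1"] = w1, _["w2"] = w2, _["w3"] = w3);
}

// Candidate cell pairs from the AABB broad phase (1-based ids).
// [[Rcpp::export]]
IntegerMatrix broad_phase_core(List pack) {
  Sim sim;
  sim.load(pack);
  if (!sim.geometry()) stop(sim.abort_reason);
  auto pairs = sim.broad_phase();
  IntegerMatrix out(pairs.size(), 2);
  for (size_t i = 0; i < pairs.size(); ++i) {
    out(i, 0) = pairs[i].first + 1;
    out(i, 1) = pairs[i].second + 1;
  }
  return out;
}
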