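// Core engine: all-atom energy model with per-residue decomposition,
// torsion-space coordinate transforms with analytic gradients, and the
// simulated-annealing sidechain packer/designer.
//
// A System holds per-residue atom coordinates (template order: N, CA, C,
// O, then sidechain), the amino-acid template database, energy weights
// and an optional restraint set.  R drives refinement through the
// exported sys_* entry points via an external pointer.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <array>
#include <string>

using namespace Rcpp;

static const double DEG = M_PI / 180.0;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  Vec3& operator+=(const Vec3& o) { x += o.x; y += o.y; z += o.z; return *this; }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
  Vec3 unit() const { double n = norm(); return Vec3(x / n, y / n, z / n); }
};

static double dihedral_deg(const Vec3& a, const Vec3& b, const Vec3& c,
                           const Vec3& d) {
  Vec3 b0 = a - b;
  Vec3 b1 = (c - b).unit();
  Vec3 b2 = d - c;
  Vec3 v = b0 - b1 * b0.dot(b1);
  Vec3 w = b2 - b1 * b2.dot(b1);
  return std::atan2(b1.cross(v).dot(w), v.dot(w)) / DEG;
}

// NeRF: place X from (a, b, c) with bond |X-c|, angle b-c-X, dihedral
// a-b-c-X (degrees)
static Vec3 place_atom(const Vec3& a, const Vec3& b, const Vec3& c,
                       double bond, double ang_deg, double dih_deg) {
  double ang = ang_deg * DEG, dih = dih_deg * DEG;
  Vec3 bc = (c - b).unit();
  Vec3 n = (b - a).cross(bc).unit();
  Vec3 m = n.cross(bc);
  double d1 = -bond * std::cos(ang);
  double d2 = bond * std::sin(ang) * std::cos(dih);
  double d3 = bond * std::sin(ang) * std::sin(dih);
  return c + bc * d1 + m * d2 + n * d3;
}

// rotate p about axis through 'origin' with unit direction u by 'rad'
static Vec3 rotate_about(const Vec3& p, const Vec3& origin, const Vec3& u,
                         double rad) {
  Vec3 v = p - origin;
  double c = std::cos(rad), s = std::sin(rad);
  Vec3 out = v * c + u.cross(v) * s + u * (u.dot(v) * (1 - c));
  return origin + out;
}

static double wrap180(double a) {
  while (a > 180.0) a -= 360.0;
  while (a <= -180.0) a += 360.0;
  return a;
}

// ---------------------------------------------------------------------------
// templates

struct AaTmpl {
  std::string aa1;
  int n_sc = 0, nchi = 0, flip_chi = 0; // flip_chi is 1-based, 0 = none
  std::vector<double> radius;           // length 4 + n_sc
  std::vector<int> ref1, ref2, ref3, dih_chi;
  std::vector<double> bond, angle, dih_off, dih_const;
  std::vector<std::array<int, 4>> chi_quads;
  std::vector<std::vector<int>> chi_dep; // per chi: list of moved sc atoms
  std::vector<std::array<int, 2>> flip_pairs;
  std::vector<std::vector<int>> gdist;   // (4+n_sc)^2 graph distance, cap 4
};

struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed * 2685821657736338717ULL + 1442695040888963407ULL) {
    for (int i = 0; i < 4; i++) next();
  }
  uint64_t next() { s ^= s << 13; s ^= s >> 7; s ^= s << 17; return s; }
  double unif() { return (double)(next() >> 11) / 9007199254740992.0; }
  int intn(int n) { int k = (int)(unif() * n); return k >= n ? n - 1 : k; }
};

struct Restraints {
  std::vector<int> c_res, c_atom, c_form, c_partner; // partner: idx or -1
  std::vector<Vec3> c_x0;
  std::vector<double> c_sd, c_width;
  std::vector<int> d_res1, d_atom1, d_res2, d_atom2;
  std::vector<double> d_d0, d_sd;
  double weight = 1.0;
};

struct System {
  int nres = 0;
  std::vector<int> aa;                  // 0-based template code
  std::vector<std::vector<Vec3>> X;     // per-residue coords
  std::vector<int> aa_orig;             // identity at construction
  std::vector<std::vector<Vec3>> sc_orig; // original sidechain coords
  std::vector<AaTmpl> db;
  double w_rep = 1, w_atr = 1, w_rot = 1, w_cst = 1;
  bool soft = false;
  double eps_atr = 0.2, soft_scale = 0.9, chi_sigma = 20.0;
  double sw_on = 4.5, sw_off = 6.0;
  Restraints rst;
  bool has_rst = false;
  // minimization snapshot
  std::vector<std::vector<Vec3>> Xbase;
  std::vector<double> theta_base;
};

// torsion catalogue entry
struct Torsion {
  int type;   // 0 phi, 1 psi, 2 chi
  int res, k; // k: 0-based chi index for type 2
  int q[8];   // quad as (res, atom) x4
};

// ---------------------------------------------------------------------------
// pair terms

// repulsive: (sigma/d)^12 - 1 inside contact, clamped to 0 outside,
// linearized below 0.6*sigma so gradients stay bounded
static inline double pow12(double t) {
  double t2 = t * t, t4 = t2 * t2;
  return t4 * t4 * t4;
}

static inline double pow6(double t) {
  double t2 = t * t;
  return t2 * t2 * t2;
}

static inline double e_rep(double d, double sigma, double* dEdd) {
  if (d >= sigma) { if (dEdd) *dEdd = 0; return 0.0; }
  double d0 = 0.6 * sigma;
  if (d >= d0) {
    double t12 = pow12(sigma / d);
    if (dEdd) *dEdd = -12.0 * t12 / d;
    return t12 - 1.0;
  }
  double t12 = pow12(1.0 / 0.6);
  double e0 = t12 - 1.0;
  double slope = -12.0 * t12 / d0;
  if (dEdd) *dEdd = slope;
  return e0 + slope * (d - d0);
}

// attractive: LJ 12-6 well of depth eps with minimum at sigma, flat
// inside, smooth-switched to zero between sw_on and sw_off
static inline double e_atr(double d, double sigma, double eps,
                           double sw_on, double sw_off, double* dEdd) {
  if (d >= sw_off) { if (dEdd) *dEdd = 0; return 0.0; }
  double e, de;
  if (d <= sigma) {
    e = -eps; de = 0;
  } else {
    double t = sigma / d;
    double t6 = pow6(t), t12 = t6 * t6;
    e = eps * (t12 - 2.0 * t6);
    de = eps * (-12.0 * t12 + 12.0 * t6) / d;
  }
  if (d > sw_on) {
    double u = (d - sw_on) / (sw_off - sw_on);
    double S = 1.0 + u * u * (2.0 * u - 3.0); // 1 -> 0, C1
    double dS = (6.0 * u * u - 6.0 * u) / (sw_off - sw_on);
    if (dEdd) *dEdd = de * S + e * dS;
    return e * S;
  }
  if (dEdd) *dEdd = de;
  return e;
}

// restraint functional forms
static inline double f_harm(double d, double sd, double* dEdd) {
  if (dEdd) *dEdd = 2.0 * d / (sd * sd);
  return (d / sd) * (d / sd);
}

static inline double f_bounded(double d, double sd, double width,
                               double* dEdd) {
  if (d <= width) { if (dEdd) *dEdd = 0; return 0.0; }
  double t = d - width;
  if (t <= 0.5 * sd) {
    if (dEdd) *dEdd = 2.0 * t / (sd * sd);
    return (t / sd) * (t / sd);
  }
  if (dEdd) *dEdd = 1.0 / sd;
  return 0.25 + (t - 0.5 * sd) / sd;
}

// rotamer-strain term for one chi: quadratic distance to the nearest
// well; terminal chis of H/N/Q treat the 180-flipped wells as equivalent
static inline double e_rot_chi(double chi, bool flip, double sigma,
                               double* dEdchi) {
  static const double wells[3] = {-60.0, 60.0, 180.0};
  double best = 1e300, bestd = 0;
  for (int i = 0; i < 3; i++) {
    double d = wrap180(chi - wells[i]);
    double e = (d / sigma) * (d / sigma);
    if (e < best) { best = e; bestd = d; }
    if (flip) {
      double d2 = wrap180(chi - wells[i] - 180.0);
      double e2 = (d2 / sigma) * (d2 / sigma);
      if (e2 < best) { best = e2; bestd = d2; }
    }
  }
  if (dEdchi) *dEdchi = 2.0 * bestd / (sigma * sigma);
  return best;
}

// ---------------------------------------------------------------------------
// exclusions: bonded graph distance <= 3.  Same residue: template table.
// Adjacent residues: through the C(i)-N(i+1) peptide bond.

static inline bool excluded(const System& S, int r1, int a1, int r2, int a2) {
  if (r1 == r2) return S.db[S.aa[r1]].gdist[a1][a2] <= 3;
  int ra = r1, aa_ = a1, rb = r2, ab = a2;
  if (r1 > r2) { ra = r2; aa_ = a2; rb = r1; ab = a1; }
  if (rb - ra != 1) return false;
  // distance = d(atom_a -> C) + 1 + d(atom_b -> N)
  int da = S.db[S.aa[ra]].gdist[aa_][2];
  int dbn = S.db[S.aa[rb]].gdist[ab][0];
  return da + 1 + dbn <= 3;
}

// ---------------------------------------------------------------------------
// full-system scoring

struct Scores {
  double rep = 0, atr = 0, rot = 0, cst = 0;
  std::vector<double> pr_rep, pr_atr, pr_rot, pr_cst;
};

static void measure_chis(const System& S, int r,
                         const std::vector<Vec3>& Xr, double* chi) {
  const AaTmpl& tp = S.db[S.aa[r]];
  for (int k = 0; k < tp.nchi; k++) {
    const std::array<int, 4>& q = tp.chi_quads[k];
    chi[k] = dihedral_deg(Xr[q[0]], Xr[q[1]], Xr[q[2]], Xr[q[3]]);
  }
}

// pair (rep/atr) energies; optionally accumulates Cartesian gradients in G
static void score_pairs(const System& S, const std::vector<std::vector<Vec3>>& X,
                        Scores& sc, std::vector<std::vector<Vec3>>* G) {
  double srep = S.soft ? S.soft_scale : 1.0;
  // residue-level culling: skip residue pairs whose atoms cannot come
  // within the attractive cutoff (CA distance minus both arm radii)
  std::vector<double> arm(S.nres, 0.0);
  for (int r = 0; r < S.nres; r++) {
    for (const Vec3& v : X[r]) {
      double a = (v - X[r][1]).norm();
      if (a > arm[r]) arm[r] = a;
    }
  }
  for (int r1 = 0; r1 < S.nres; r1++) {
    const AaTmpl& t1 = S.db[S.aa[r1]];
    int n1 = 4 + t1.n_sc;
    for (int r2 = r1; r2 < S.nres; r2++) {
      const AaTmpl& t2 = S.db[S.aa[r2]];
      int n2 = 4 + t2.n_sc;
      if (r2 > r1) {
        double gap = (X[r2][1] - X[r1][1]).norm() - arm[r1] - arm[r2];
        if (gap >= S.sw_off) continue;
      }
      for (int a1 = 0; a1 < n1; a1++) {
        int a2start = (r1 == r2) ? a1 + 1 : 0;
        for (int a2 = a2start; a2 < n2; a2++) {
          Vec3 dv = X[r2][a2] - X[r1][a1];
          double d2 = dv.dot(dv);
          if (d2 >= S.sw_off * S.sw_off) continue;
          if (excluded(S, r1, a1, r2, a2)) continue;
          double d = std::sqrt(d2);
          double sigma = t1.radius[a1] + t2.radius[a2];
          double drep = 0, datr = 0;
          double er = e_rep(d, sigma * srep, G ? &drep : 0);
          double ea = e_atr(d, sigma, S.eps_atr, S.sw_on, S.sw_off,
                            G ? &datr : 0);
          sc.rep += er; sc.atr += ea;
          sc.pr_rep[r1] += 0.5 * er; sc.pr_rep[r2] += 0.5 * er;
          sc.pr_atr[r1] += 0.5 * ea; sc.pr_atr[r2] += 0.5 * ea;
          if (G) {
            double f = (S.w_rep * drep + S.w_atr * datr) / d;
            Vec3 g = dv * f;
            (*G)[r2][a2] += g;
            (*G)[r1][a1] += g * (-1.0);
          }
        }
      }
    }
  }
}

static void score_rot(const System& S, const std::vector<std::vector<Vec3>>& X,
                      Scores& sc) {
  double chi[8];
  for (int r = 0; r < S.nres; r++) {
    const AaTmpl& tp = S.db[S.aa[r]];
    if (tp.nchi == 0) continue;
    measure_chis(S, r, X[r], chi);
    for (int k = 0; k < tp.nchi; k++) {
      double e = e_rot_chi(chi[k], tp.flip_chi == k + 1, S.chi_sigma, 0);
      sc.rot += e;
      sc.pr_rot[r] += e;
    }
  }
}

// restraint energy (unweighted by w_cst but including the set weight);
// optionally accumulates WEIGHTED gradients (w_cst folded in) into G
static void score_cst(const System& S, const std::vector<std::vector<Vec3>>& X,
                      Scores& sc, std::vector<std::vector<Vec3>>* G) {
  if (!S.has_rst) return;
  const Restraints& R = S.rst;
  double w = R.weight;
  double gw = S.w_cst * w;
  // coordinate restraints; flip-aware pairs evaluated as a group
  size_t nc = R.c_res.size();
  for (size_t i = 0; i < nc; i++) {
    int p = R.c_partner[i];
    if (p >= 0 && p < (int)i) continue; // handled with its partner
    int r = R.c_res[i], a = R.c_atom[i];
    const Vec3& x = X[r][a];
    auto one = [&](const Vec3& xx, const Vec3& x0, double sd, double width,
                   int form, double* dEdd, Vec3* dir) -> double {
      Vec3 dv = xx - x0;
      double d = dv.norm();
      double e = (form == 0) ? f_harm(d, sd, dEdd)
                             : f_bounded(d, sd, width, dEdd);
      if (dir) *dir = (d > 1e-12) ? dv * (1.0 / d) : Vec3(0, 0, 0);
      return e;
    };
    if (p < 0) {
      double dEdd; Vec3 dir;
      double e = one(x, R.c_x0[i], R.c_sd[i], R.c_width[i], R.c_form[i],
                     &dEdd, &dir);
      sc.cst += w * e;
      sc.pr_cst[r] += w * e;
      if (G) (*G)[r][a] += dir * (dEdd * gw);
    } else {
      // evaluate direct and swapped target assignment, keep the lower
      int r2 = R.c_res[p], a2 = R.c_atom[p];
      const Vec3& y = X[r2][a2];
      double dE1a, dE1b, dE2a, dE2b;
      Vec3 u1a, u1b, u2a, u2b;
      double e_dir = one(x, R.c_x0[i], R.c_sd[i], R.c_width[i], R.c_form[i], &dE1a, &u1a)
                   + one(y, R.c_x0[p], R.c_sd[p], R.c_width[p], R.c_form[p], &dE1b, &u1b);
      double e_swp = one(x, R.c_x0[p], R.c_sd[i], R.c_width[i], R.c_form[i], &dE2a, &u2a)
                   + one(y, R.c_x0[i], R.c_sd[p], R.c_width[p], R.c_form[p], &dE2b, &u2b);
      if (e_dir <= e_swp) {
        sc.cst += w * e_dir;
        sc.pr_cst[r] += 0.5 * w * e_dir; sc.pr_cst[r2] += 0.5 * w * e_dir;
        if (G) { (*G)[r][a] += u1a * (dE1a * gw); (*G)[r2][a2] += u1b * (dE1b * gw); }
      } else {
        sc.cst += w * e_swp;
        sc.pr_cst[r] += 0.5 * w * e_swp; sc.pr_cst[r2] += 0.5 * w * e_swp;
        if (G) { (*G)[r][a] += u2a * (dE2a * gw); (*G)[r2][a2] += u2b * (dE2b * gw); }
      }
    }
  }
  // distance restraints: harmonic in |d - d0|
  size_t nd = R.d_res1.size();
  for (size_t i = 0; i < nd; i++) {
    int r1 = R.d_res1[i], a1 = R.d_atom1[i];
    int r2 = R.d_res2[i], a2 = R.d_atom2[i];
    Vec3 dv = X[r2][a2] - X[r1][a1];
    double d = dv.norm();
    double dev = d - R.d_d0[i];
    double sd = R.d_sd[i];
    double e = (dev / sd) * (dev / sd);
    sc.cst += w * e;
    sc.pr_cst[r1] += 0.5 * w * e; sc.pr_cst[r2] += 0.5 * w * e;
    if (G && d > 1e-12) {
      Vec3 g = dv * (gw * 2.0 * dev / (sd * sd) / d);
      (*G)[r2][a2] += g; (*G)[r1][a1] += g * (-1.0);
    }
  }
}

static Scores score_all(const System& S, const std::vector<std::vector<Vec3>>& X,
                        std::vector<std::vector<Vec3>>* G) {
  Scores sc;
  sc.pr_rep.assign(S.nres, 0); sc.pr_atr.assign(S.nres, 0);
  sc.pr_rot.assign(S.nres, 0); sc.pr_cst.assign(S.nres, 0);
  score_pairs(S, X, sc, G);
  score_rot(S, X, sc);
  score_cst(S, X, sc, G);
  return sc;
}

static double total_of(const System& S, const Scores& sc) {
  return S.w_rep * sc.rep + S.w_atr * sc.atr + S.w_rot * sc.rot +
         S.w_cst * sc.cst;
}

// ---------------------------------------------------------------------------
// torsion catalogue

static std::vector<Torsion> torsion_list(const System& S) {
  std::vector<Torsion> ts;
  for (int r = 0; r < S.nres; r++) {
    const AaTmpl& tp = S.db[S.aa[r]];
    if (r > 0) { // phi: C(r-1), N, CA, C
      Torsion t; t.type = 0; t.res = r; t.k = -1;
      int q[8] = {r - 1, 2, r, 0, r, 1, r, 2};
      std::copy(q, q + 8, t.q);
      ts.push_back(t);
    }
    { // psi: N, CA, C, N(r+1)  (terminal residue: ..., O)
      Torsion t; t.type = 1; t.res = r; t.k = -1;
      if (r < S.nres - 1) {
        int q[8] = {r, 0, r, 1, r, 2, r + 1, 0};
        std::copy(q, q + 8, t.q);
      } else {
        int q[8] = {r, 0, r, 1, r, 2, r, 3};
        std::copy(q, q + 8, t.q);
      }
      ts.push_back(t);
    }
    for (int k = 0; k < tp.nchi; k++) {
      Torsion t; t.type = 2; t.res = r; t.k = k;
      const std::array<int, 4>& cq = tp.chi_quads[k];
      int q[8] = {r, cq[0], r, cq[1], r, cq[2], r, cq[3]};
      std::copy(q, q + 8, t.q);
      ts.push_back(t);
    }
  }
  return ts;
}

static double measure_torsion(const std::vector<std::vector<Vec3>>& X,
                              const Torsion& t) {
  return dihedral_deg(X[t.q[0]][t.q[1]], X[t.q[2]][t.q[3]],
                      X[t.q[4]][t.q[5]], X[t.q[6]][t.q[7]]);
}

// iterate over atoms moved by torsion t (downstream convention: rotating
// a torsion moves the chain toward the C-terminus plus, for phi, the
// residue's own sidechain and carbonyl)
template <typename F>
static void for_each_moved(const System& S, const Torsion& t, F f) {
  if (t.type == 0) { // phi: C, O, sidechain of res; all later residues
    const AaTmpl& tp = S.db[S.aa[t.res]];
    f(t.res, 2); f(t.res, 3);
    for (int a = 4; a < 4 + tp.n_sc; a++) f(t.res, a);
    for (int r = t.res + 1; r < S.nres; r++) {
      int n = 4 + S.db[S.aa[r]].n_sc;
      for (int a = 0; a < n; a++) f(r, a);
    }
  } else if (t.type == 1) { // psi: O of res; all later residues
    f(t.res, 3);
    for (int r = t.res + 1; r < S.nres; r++) {
      int n = 4 + S.db[S.aa[r]].n_sc;
      for (int a = 0; a < n; a++) f(r, a);
    }
  } else { // chi k: dependent sidechain atoms
    const AaTmpl& tp = S.db[S.aa[t.res]];
    for (int a : tp.chi_dep[t.k]) f(t.res, a);
  }
}

// apply theta (degrees) relative to (Xbase, theta_base); torsions are
// processed in catalogue order so axis atoms are already up to date
static std::vector<std::vector<Vec3>> apply_torsions(
    const System& S, const std::vector<Torsion>& ts,
    const std::vector<double>& theta) {
  std::vector<std::vector<Vec3>> X = S.Xbase;
  for (size_t i = 0; i < ts.size(); i++) {
    double delta = theta[i] - S.theta_base[i];
    if (std::fabs(delta) < 1e-13) continue;
    const Torsion& t = ts[i];
    Vec3 p = X[t.q[2]][t.q[3]]; // axis: second -> third quad atom
    Vec3 q = X[t.q[4]][t.q[5]];
    Vec3 u = (q - p).unit();
    double rad = delta * DEG;
    for_each_moved(S, t, [&](int r, int a) {
      X[r][a] = rotate_about(X[r][a], p, u, rad);
    });
  }
  return X;
}

// ---------------------------------------------------------------------------
// R interface helpers

static AaTmpl parse_tmpl(List L) {
  AaTmpl t;
  t.aa1 = as<std::string>(L["aa1"]);
  t.n_sc = as<int>(L["n_sc"]);
  t.nchi = as<int>(L["nchi"]);
  t.flip_chi = as<int>(L["flip_chi"]);
  t.radius = as<std::vector<double>>(L["radius"]);
  t.ref1 = as<std::vector<int>>(L["ref1"]);
  t.ref2 = as<std::vector<int>>(L["ref2"]);
  t.ref3 = as<std::vector<int>>(L["ref3"]);
  t.bond = as<std::vector<double>>(L["bond"]);
  t.angle = as<std::vector<double>>(L["angle"]);
  t.dih_chi = as<std::vector<int>>(L["dih_chi"]);
  t.dih_off = as<std::vector<double>>(L["dih_off"]);
  t.dih_const = as<std::vector<double>>(L["dih_const"]);
  IntegerMatrix cq = L["chi_quads"];
  for (int i = 0; i < cq.nrow(); i++) {
    t.chi_quads.push_back({cq(i, 0), cq(i, 1), cq(i, 2), cq(i, 3)});
  }
  LogicalMatrix dep = L["chi_dep"];
  t.chi_dep.assign(t.nchi, {});
  for (int k = 0; k < t.nchi; k++) {
    for (int a = 0; a < dep.nrow(); a++) {
      if (dep(a, k)) t.chi_dep[k].push_back(a);
    }
  }
  IntegerMatrix fp = L["flip_pairs"];
  for (int i = 0; i < fp.nrow(); i++) {
    t.flip_pairs.push_back({fp(i, 0), fp(i, 1)});
  }
  IntegerMatrix gd = L["gdist"];
  t.gdist.assign(gd.nrow(), std::vector<int>(gd.ncol()));
  for (int i = 0; i < gd.nrow(); i++) {
    for (int j = 0; j < gd.ncol(); j++) t.gdist[i][j] = gd(i, j);
  }
  return t;
}

// [[Rcpp::export(name = ".sys_new")]]
SEXP sys_new(IntegerVector aa_code, NumericMatrix xyz, List tmpl_db,
             List params) {
  System* S = new System();
  for (int i = 0; i < tmpl_db.size(); i++) {
    S->db.push_back(parse_tmpl(tmpl_db[i]));
  }
  S->nres = aa_code.size();
  S->aa.resize(S->nres);
  S->X.assign(S->nres, {});
  int row = 0;
  for (int r = 0; r < S->nres; r++) {
    S->aa[r] = aa_code[r] - 1;
    int n = 4 + S->db[S->aa[r]].n_sc;
    for (int a = 0; a < n; a++) {
      S->X[r].push_back(Vec3(xyz(row, 0), xyz(row, 1), xyz(row, 2)));
      row++;
    }
  }
  if (row != xyz.nrow()) {
    delete S;
    stop("coordinate count does not match the residue templates");
  }
  S->aa_orig = S->aa;
  S->sc_orig.assign(S->nres, {});
  for (int r = 0; r < S->nres; r++) {
    S->sc_orig[r].assign(S->X[r].begin() + 4, S->X[r].end());
  }
  S->eps_atr = as<double>(params["eps_atr"]);
  S->soft_scale = as<double>(params["soft_scale"]);
  S->chi_sigma = as<double>(params["chi_sigma"]);
  S->sw_on = as<double>(params["sw_on"]);
  S->sw_off = as<double>(params["sw_off"]);
  XPtr<System> ptr(S, true);
  return ptr;
}

// [[Rcpp::export(name = ".sys_set_weights")]]
void sys_set_weights(SEXP sysp, double w_rep, double w_atr, double w_rot,
                     double w_cst, bool soft) {
  XPtr<System> S(sysp);
  S->w_rep = w_rep; S->w_atr = w_atr; S->w_rot = w_rot; S->w_cst = w_cst;
  S->soft = soft;
}

// [[Rcpp::export(name = ".sys_set_restraints")]]
void sys_set_restraints(SEXP sysp, List cst) {
  XPtr<System> S(sysp);
  Restraints R;
  if (cst.containsElementNamed("c_res")) {
    R.c_res = as<std::vector<int>>(cst["c_res"]);
    R.c_atom = as<std::vector<int>>(cst["c_atom"]);
    R.c_form = as<std::vector<int>>(cst["c_form"]);
    R.c_partner = as<std::vector<int>>(cst["c_partner"]);
    R.c_sd = as<std::vector<double>>(cst["c_sd"]);
    R.c_width = as<std::vector<double>>(cst["c_width"]);
    NumericMatrix x0 = cst["c_x0"];
    for (int i = 0; i < x0.nrow(); i++) {
      R.c_x0.push_back(Vec3(x0(i, 0), x0(i, 1), x0(i, 2)));
    }
  }
  if (cst.containsElementNamed("d_res1")) {
    R.d_res1 = as<std::vector<int>>(cst["d_res1"]);
    R.d_atom1 = as<std::vector<int>>(cst["d_atom1"]);
    R.d_res2 = as<std::vector<int>>(cst["d_res2"]);
    R.d_atom2 = as<std::vector<int>>(cst["d_atom2"]);
    R.d_d0 = as<std::vector<double>>(cst["d_d0"]);
    R.d_sd = as<std::vector<double>>(cst["d_sd"]);
  }
  R.weight = as<double>(cst["weight"]);
  S->rst = R;
  S->has_rst = true;
}

// [[Rcpp::export(name = ".sys_clear_restraints")]]
void sys_clear_restraints(SEXP sysp) {
  XPtr<System> S(sysp);
  S->has_rst = false;
}

// [[Rcpp::export(name = ".sys_set_cst_weight")]]
void sys_set_cst_weight(SEXP sysp, double weight) {
  XPtr<System> S(sysp);
  S->rst.weight = weight;
}

// [[Rcpp::export(name = ".sys_score")]]
List sys_score(SEXP sysp) {
  XPtr<System> S(sysp);
  for (int r = 0; r < S->nres; r++) {
    for (const Vec3& v : S->X[r]) {
      if (!std::isfinite(v.x) || !std::isfinite(v.y) || !std::isfinite(v.z)) {
        stop("non-finite coordinates");
      }
    }
  }
  Scores sc = score_all(*S, S->X, 0);
  NumericMatrix pr(S->nres, 4);
  for (int r = 0; r < S->nres; r++) {
    pr(r, 0) = S->w_rep * sc.pr_rep[r];
    pr(r, 1) = S->w_atr * sc.pr_atr[r];
    pr(r, 2) = S->w_rot * sc.pr_rot[r];
    pr(r, 3) = S->w_cst * sc.pr_cst[r];
  }
  colnames(pr) = CharacterVector::create("rep", "atr", "rot", "cst");
  return List::create(
    _["total"] = total_of(*S, sc),
    _["terms"] = NumericVector::create(
      _["rep"] = S->w_rep * sc.rep, _["atr"] = S->w_atr * sc.atr,
      _["rot"] = S->w_rot * sc.rot, _["cst"] = S->w_cst * sc.cst),
    _["raw_terms"] = NumericVector::create(
      _["rep"] = sc.rep, _["atr"] = sc.atr,
      _["rot"] = sc.rot, _["cst"] = sc.cst),
    _["by_residue"] = pr);
}

// [[Rcpp::export(name = ".sys_get_xyz")]]
NumericMatrix sys_get_xyz(SEXP sysp) {
  XPtr<System> S(sysp);
  int n = 0;
  for (int r = 0; r < S->nres; r++) n += (int)S->X[r].size();
  NumericMatrix out(n, 3);
  int row = 0;
  for (int r = 0; r < S->nres; r++) {
    for (const Vec3& v : S->X[r]) {
      out(row, 0) = v.x; out(row, 1) = v.y; out(row, 2) = v.z;
      row++;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".sys_set_xyz")]]
void sys_set_xyz(SEXP sysp, NumericMatrix xyz) {
  XPtr<System> S(sysp);
  int row = 0;
  for (int r = 0; r < S->nres; r++) {
    for (Vec3& v : S->X[r]) {
      if (row >= xyz.nrow()) stop("coordinate matrix too short");
      v = Vec3(xyz(row, 0), xyz(row, 1), xyz(row, 2));
      row++;
    }
  }
  if (row != xyz.nrow()) stop("coordinate matrix size mismatch");
}

// [[Rcpp::export(name = ".sys_aa")]]
IntegerVector sys_aa(SEXP sysp) {
  XPtr<System> S(sysp);
  IntegerVector out(S->nres);
  for (int r = 0; r < S->nres; r++) out[r] = S->aa[r] + 1;
  return out;
}

// [[Rcpp::export(name = ".sys_torsions")]]
DataFrame sys_torsions(SEXP sysp) {
  XPtr<System> S(sysp);
  std::vector<Torsion> ts = torsion_list(*S);
  int n = (int)ts.size();
  IntegerVector type(n), res(n), k(n);
  NumericVector value(n);
  for (int i = 0; i < n; i++) {
    type[i] = ts[i].type;
    res[i] = ts[i].res + 1;
    k[i] = ts[i].k + 1;
    value[i] = measure_torsion(S->X, ts[i]);
  }
  return DataFrame::create(
    _["type"] = type, _["res"] = res, _["chi"] = k, _["value"] = value);
}

// [[Rcpp::export(name = ".sys_min_begin")]]
NumericVector sys_min_begin(SEXP sysp) {
  XPtr<System> S(sysp);
  std::vector<Torsion> ts = torsion_list(*S);
  S->Xbase = S->X;
  S->theta_base.resize(ts.size());
  NumericVector out(ts.size());
  for (size_t i = 0; i < ts.size(); i++) {
    S->theta_base[i] = measure_torsion(S->Xbase, ts[i]);
    out[i] = S->theta_base[i];
  }
  return out;
}

// energy and gradient (units per degree) at torsion vector theta
// [[Rcpp::export(name = ".sys_energy_grad")]]
List sys_energy_grad(SEXP sysp, NumericVector theta) {
  XPtr<System> S(sysp);
  std::vector<Torsion> ts = torsion_list(*S);
  if ((int)ts.size() != theta.size()) stop("torsion vector length mismatch");
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<std::vector<Vec3>> X = apply_torsions(*S, ts, th);

  std::vector<std::vector<Vec3>> G(S->nres);
  for (int r = 0; r < S->nres; r++) G[r].assign(S->X[r].size(), Vec3());

  Scores sc;
  sc.pr_rep.assign(S->nres, 0); sc.pr_atr.assign(S->nres, 0);
  sc.pr_rot.assign(S->nres, 0); sc.pr_cst.assign(S->nres, 0);
  score_pairs(*S, X, sc, &G);
  score_cst(*S, X, sc, &G);

  // rotamer strain evaluated directly in torsion space
  NumericVector grad(theta.size());
  double E = S->w_rep * sc.rep + S->w_atr * sc.atr + S->w_cst * sc.cst;
  for (size_t i = 0; i < ts.size(); i++) {
    const Torsion& t = ts[i];
    if (t.type == 2) {
      const AaTmpl& tp = S->db[S->aa[t.res]];
      double dE;
      double e = e_rot_chi(th[i], tp.flip_chi == t.k + 1, S->chi_sigma, &dE);
      E += S->w_rot * e;
      grad[i] += S->w_rot * dE;
    }
  }
  // chain-rule torsion gradients from the Cartesian gradient
  for (size_t i = 0; i < ts.size(); i++) {
    const Torsion& t = ts[i];
    Vec3 p = X[t.q[2]][t.q[3]];
    Vec3 q = X[t.q[4]][t.q[5]];
    Vec3 u = (q - p).unit();
    double g = 0;
    for_each_moved(*S, t, [&](int r, int a) {
      Vec3 arm = X[r][a] - p;
      g += u.cross(arm).dot(G[r][a]);
    });
    grad[i] += g * DEG; // per degree
  }
  if (!std::isfinite(E)) stop("non-finite energy during minimization");
  return List::create(_["E"] = E, _["grad"] = grad);
}

// [[Rcpp::export(name = ".sys_min_commit")]]
void sys_min_commit(SEXP sysp, NumericVector theta) {
  XPtr<System> S(sysp);
  std::vector<Torsion> ts = torsion_list(*S);
  if ((int)ts.size() != theta.size()) stop("torsion vector length mismatch");
  std::vector<double> th(theta.begin(), theta.end());
  S->X = apply_torsions(*S, ts, th);
  S->Xbase.clear();
  S->theta_base.clear();
}

// ---------------------------------------------------------------------------
// sidechain rotation / construction

// rotate existing sidechain of residue r so its chis equal 'target'
static void set_chi_inplace(System& S, int r, const double* target) {
  const AaTmpl& tp = S.db[S.aa[r]];
  double cur[8];
  for (int k = 0; k < tp.nchi; k++) {
    const std::array<int, 4>& q = tp.chi_quads[k];
    cur[k] = dihedral_deg(S.X[r][q[0]], S.X[r][q[1]], S.X[r][q[2]],
                          S.X[r][q[3]]);
    double delta = wrap180(target[k] - cur[k]);
    if (std::fabs(delta) < 1e-12) continue;
    Vec3 p = S.X[r][q[1]];
    Vec3 ax = (S.X[r][q[2]] - p).unit();
    double rad = delta * DEG;
    for (int a : tp.chi_dep[k]) {
      S.X[r][a] = rotate_about(S.X[r][a], p, ax, rad);
    }
  }
}

// build an ideal-geometry sidechain for amino acid 'code' on the backbone
// of residue r, at chi values 'chi'; returns sidechain coords
static std::vector<Vec3> build_sc(const System& S, int r, int code,
                                  const double* chi) {
  const AaTmpl& tp = S.db[code];
  std::vector<Vec3> res(S.X[r].begin(), S.X[r].begin() + 4);
  res.resize(4 + tp.n_sc);
  for (int j = 0; j < tp.n_sc; j++) {
    double dih = (tp.dih_chi[j] > 0) ? chi[tp.dih_chi[j] - 1] + tp.dih_off[j]
                                     : tp.dih_const[j];
    res[4 + j] = place_atom(res[tp.ref1[j]], res[tp.ref2[j]], res[tp.ref3[j]],
                            tp.bond[j], tp.angle[j], dih);
  }
  return std::vector<Vec3>(res.begin() + 4, res.end());
}

// [[Rcpp::export(name = ".sys_set_chi")]]
void sys_set_chi(SEXP sysp, int res, NumericVector chi) {
  XPtr<System> S(sysp);
  int r = res - 1;
  const AaTmpl& tp = S->db[S->aa[r]];
  if ((int)chi.size() != tp.nchi) stop("chi vector length mismatch");
  if (tp.nchi == 0) return;
  std::vector<double> t(chi.begin(), chi.end());
  set_chi_inplace(*S, r, t.data());
}

// ---------------------------------------------------------------------------
// packer: simulated annealing over rotamers (and identities, for design)

// environment energy of residue r given trial sidechain coords scX and
// identity 'code'; chi may be NULL (measured from scX)
static double res_env_energy(const System& S, int r, int code,
                             const std::vector<Vec3>& scX,
                             const double* chi_in) {
  const AaTmpl& tp = S.db[code];
  double srep = S.soft ? S.soft_scale : 1.0;
  double E = 0;
  // rotamer strain
  double chi[8];
  if (tp.nchi > 0) {
    if (chi_in) {
      for (int k = 0; k < tp.nchi; k++) chi[k] = chi_in[k];
    } else {
      std::vector<Vec3> full(S.X[r].begin(), S.X[r].begin() + 4);
      full.insert(full.end(), scX.begin(), scX.end());
      for (int k = 0; k < tp.nchi; k++) {
        const std::array<int, 4>& q = tp.chi_quads[k];
        chi[k] = dihedral_deg(full[q[0]], full[q[1]], full[q[2]], full[q[3]]);
      }
    }
    for (int k = 0; k < tp.nchi; k++) {
      E += S.w_rot * e_rot_chi(chi[k], tp.flip_chi == k + 1, S.chi_sigma, 0);
    }
  }
  // pair terms: sidechain atoms vs everything else
  auto pair_e = [&](const Vec3& xa, double ra_, const Vec3& xb, double rb_) {
    Vec3 dv = xb - xa;
    double d2 = dv.dot(dv);
    if (d2 >= S.sw_off * S.sw_off) return 0.0;
    double d = std::sqrt(d2);
    double sigma = ra_ + rb_;
    return S.w_rep * e_rep(d, sigma * srep, 0) +
           S.w_atr * e_atr(d, sigma, S.eps_atr, S.sw_on, S.sw_off, 0);
  };
  for (int a = 0; a < tp.n_sc; a++) {
    int ai = 4 + a;
    const Vec3& xa = scX[a];
    double ra_ = tp.radius[ai];
    // own backbone + intra sidechain
    for (int b = 0; b < 4 + tp.n_sc; b++) {
      if (b >= 4 && b - 4 <= a) continue; // intra sc pairs counted once
      if (tp.gdist[ai][b] <= 3) continue;
      const Vec3& xb = (b < 4) ? S.X[r][b] : scX[b - 4];
      E += pair_e(xa, ra_, xb, tp.radius[b]);
    }
    // other residues
    for (int r2 = 0; r2 < S.nres; r2++) {
      if (r2 == r) continue;
      const AaTmpl& t2 = S.db[S.aa[r2]];
      int n2 = 4 + t2.n_sc;
      bool adj = std::abs(r2 - r) == 1;
      for (int b = 0; b < n2; b++) {
        if (adj) {
          int d13;
          if (r2 > r) d13 = tp.gdist[ai][2] + 1 + t2.gdist[b][0];
          else d13 = t2.gdist[b][2] + 1 + tp.gdist[ai][0];
          if (d13 <= 3) continue;
        }
        E += pair_e(xa, ra_, S.X[r2][b], t2.radius[b]);
      }
    }
  }
  // restraints touching this sidechain (only meaningful while the residue
  // keeps its original identity; design runs carry no restraint set)
  if (S.has_rst && code == S.aa_orig[r]) {
    const Restraints& R = S.rst;
    double w = S.w_cst * R.weight;
    auto coord_e = [&](size_t i, const Vec3& x, const Vec3& x0) {
      double d = (x - x0).norm();
      return (R.c_form[i] == 0) ? f_harm(d, R.c_sd[i], 0)
                                : f_bounded(d, R.c_sd[i], R.c_width[i], 0);
    };
    for (size_t i = 0; i < R.c_res.size(); i++) {
      if (R.c_res[i] != r || R.c_atom[i] < 4) continue;
      int p = R.c_partner[i];
      if (p >= 0 && p < (int)i) continue;
      const Vec3& x = scX[R.c_atom[i] - 4];
      if (p < 0) {
        E += w * coord_e(i, x, R.c_x0[i]);
      } else {
        const Vec3& y = scX[R.c_atom[p] - 4];
        double e_dir = coord_e(i, x, R.c_x0[i]) + coord_e(p, y, R.c_x0[p]);
        double e_swp = coord_e(i, x, R.c_x0[p]) + coord_e(p, y, R.c_x0[i]);
        E += w * std::min(e_dir, e_swp);
      }
    }
    for (size_t i = 0; i < R.d_res1.size(); i++) {
      bool in1 = (R.d_res1[i] == r && R.d_atom1[i] >= 4);
      bool in2 = (R.d_res2[i] == r && R.d_atom2[i] >= 4);
      if (!in1 && !in2) continue;
      Vec3 x1 = in1 ? scX[R.d_atom1[i] - 4] : S.X[R.d_res1[i]][R.d_atom1[i]];
      Vec3 x2 = in2 ? scX[R.d_atom2[i] - 4] : S.X[R.d_res2[i]][R.d_atom2[i]];
      double dev = (x2 - x1).norm() - R.d_d0[i];
      E += w * (dev / R.d_sd[i]) * (dev / R.d_sd[i]);
    }
  }
  return E;
}

// enumerate chi-well combinations for one template
static std::vector<std::vector<double>> chi_combos(const AaTmpl& tp,
                                                   bool flip, bool ex) {
  std::vector<std::vector<double>> per_chi;
  for (int k = 0; k < tp.nchi; k++) {
    std::vector<double> v = {-60.0, 60.0, 180.0};
    if (flip && tp.flip_chi == k + 1) {
      v.push_back(0.0); v.push_back(120.0); v.push_back(-120.0);
    }
    if (ex) {
      size_t n0 = v.size();
      for (size_t i = 0; i < n0; i++) {
        v.push_back(v[i] - 10.0);
        v.push_back(v[i] + 10.0);
      }
    }
    per_chi.push_back(v);
  }
  std::vector<std::vector<double>> out;
  out.push_back({});
  for (int k = 0; k < tp.nchi; k++) {
    std::vector<std::vector<double>> nxt;
    for (const auto& base : out) {
      for (double val : per_chi[k]) {
        std::vector<double> c = base;
        c.push_back(val);
        nxt.push_back(c);
      }
    }
    out = nxt;
  }
  return out;
}

struct Candidate {
  int code;                 // amino-acid template code
  std::vector<Vec3> scX;    // sidechain coordinates
  std::vector<double> chi;  // chi values (may be empty -> measure)
};

// build candidate list for residue r; 'allowed' lists identities for
// design positions (repack positions pass only the current identity)
static std::vector<Candidate> make_candidates(const System& S, int r,
                                              const std::vector<int>& allowed,
                                              bool flip, bool ex) {
  std::vector<Candidate> cands;
  int cur = S.aa[r];
  // current coordinates (use-input-rotamer)
  {
    Candidate c;
    c.code = cur;
    c.scX.assign(S.X[r].begin() + 4, S.X[r].end());
    cands.push_back(c);
  }
  // original (native) rotamer, if identity or coordinates changed
  if (S.aa_orig[r] != cur) {
    Candidate c;
    c.code = S.aa_orig[r];
    c.scX = S.sc_orig[r];
    cands.push_back(c);
  }
  for (int code : allowed) {
    const AaTmpl& tp = S.db[code];
    if (tp.nchi == 0) {
      if (code != cur) { // e.g. mutate to GLY/ALA/PRO
        Candidate c;
        c.code = code;
        double chi0[1] = {0};
        c.scX = build_sc(S, r, code, chi0);
        cands.push_back(c);
      }
      continue;
    }
    std::vector<std::vector<double>> combos = chi_combos(tp, flip, ex);
    for (auto& chi : combos) {
      Candidate c;
      c.code = code;
      c.chi = chi;
      if (code == cur) {
        // rotate the existing sidechain (preserves its internal geometry)
        // via a temporary copy of the system residue
        c.scX.assign(S.X[r].begin() + 4, S.X[r].end());
        // measure current chis and rotate
        std::vector<Vec3> full(S.X[r].begin(), S.X[r].begin() + 4);
        full.insert(full.end(), c.scX.begin(), c.scX.end());
        for (int k = 0; k < tp.nchi; k++) {
          const std::array<int, 4>& q = tp.chi_quads[k];
          double curchi = dihedral_deg(full[q[0]], full[q[1]], full[q[2]],
                                       full[q[3]]);
          double delta = wrap180(chi[k] - curchi);
          if (std::fabs(delta) < 1e-12) continue;
          Vec3 p = full[q[1]];
          Vec3 ax = (full[q[2]] - p).unit();
          for (int a : tp.chi_dep[k]) {
            full[a] = rotate_about(full[a], p, ax, delta * DEG);
          }
        }
        c.scX.assign(full.begin() + 4, full.end());
      } else {
        c.scX = build_sc(S, r, code, chi.data());
      }
      cands.push_back(c);
    }
  }
  return cands;
}

// [[Rcpp::export(name = ".sys_pack")]]
List sys_pack(SEXP sysp, IntegerVector repack_res, IntegerVector design_res,
              List allowed_codes, bool flip, bool ex, NumericVector temps,
              int seed, NumericVector aa_ref) {
  XPtr<System> S(sysp);
  RNG rng((uint64_t)seed);
  // per-identity reference energy (chemical-potential-like; constant per
  // composition, so it only matters where identities may change)
  std::vector<double> ref(S->db.size(), 0.0);
  for (int i = 0; i < aa_ref.size() && i < (int)ref.size(); i++) {
    ref[i] = aa_ref[i];
  }

  struct Pos { int r; std::vector<int> allowed; };
  std::vector<Pos> pos;
  for (int i = 0; i < repack_res.size(); i++) {
    Pos p; p.r = repack_res[i] - 1;
    p.allowed = {S->aa[p.r]};
    pos.push_back(p);
  }
  for (int i = 0; i < design_res.size(); i++) {
    Pos p; p.r = design_res[i] - 1;
    IntegerVector al = allowed_codes[i];
    for (int j = 0; j < al.size(); j++) p.allowed.push_back(al[j] - 1);
    pos.push_back(p);
  }
  // skip residues with nothing to move (no chi and a single identity)
  std::vector<Pos> act;
  for (auto& p : pos) {
    bool movable = p.allowed.size() > 1;
    for (int code : p.allowed) {
      if (S->db[code].nchi > 0) movable = true;
    }
    if (S->db[S->aa[p.r]].nchi > 0) movable = true;
    if (movable) act.push_back(p);
  }

  auto apply = [&](int r, const Candidate& c) {
    S->aa[r] = c.code;
    S->X[r].resize(4);
    S->X[r].insert(S->X[r].end(), c.scX.begin(), c.scX.end());
  };

  // annealing with Metropolis acceptance, then a zero-temperature greedy
  // sweep (repeated to quiescence) that guarantees no uphill final moves
  for (int ti = 0; ti < temps.size(); ti++) {
    double T = temps[ti];
    for (auto& p : act) {
      std::vector<Candidate> cands = make_candidates(*S, p.r, p.allowed,
                                                     flip, ex);
      std::vector<Vec3> cur_sc(S->X[p.r].begin() + 4, S->X[p.r].end());
      double e_cur = res_env_energy(*S, p.r, S->aa[p.r], cur_sc, 0) +
                     ref[S->aa[p.r]];
      if (T > 0) {
        int nprop = (int)cands.size();
        for (int it = 0; it < nprop; it++) {
          Candidate c = cands[rng.intn((int)cands.size())];
          double e_new = res_env_energy(*S, p.r, c.code, c.scX,
                                        c.chi.empty() ? 0 : c.chi.data()) +
                         ref[c.code];
          double dE = e_new - e_cur;
          if (dE <= 0 || rng.unif() < std::exp(-dE / T)) {
            bool id_change = (c.code != S->aa[p.r]);
            apply(p.r, c);
            e_cur = e_new;
            if (id_change) {
              cands = make_candidates(*S, p.r, p.allowed, flip, ex);
            }
          }
        }
      } else {
        int best = -1;
        double e_best = e_cur;
        for (size_t ci = 0; ci < cands.size(); ci++) {
          double e_new = res_env_energy(*S, p.r, cands[ci].code,
                                        cands[ci].scX,
                                        cands[ci].chi.empty()
                                            ? 0 : cands[ci].chi.data()) +
                         ref[cands[ci].code];
          if (e_new < e_best - 1e-12) { e_best = e_new; best = (int)ci; }
        }
        if (best >= 0) apply(p.r, cands[best]);
      }
    }
  }
  // greedy sweeps to quiescence
  for (int sweep = 0; sweep < 3; sweep++) {
    bool changed = false;
    for (auto& p : act) {
      std::vector<Candidate> cands = make_candidates(*S, p.r, p.allowed,
                                                     flip, ex);
      std::vector<Vec3> cur_sc(S->X[p.r].begin() + 4, S->X[p.r].end());
      double e_best = res_env_energy(*S, p.r, S->aa[p.r], cur_sc, 0) +
                      ref[S->aa[p.r]];
      int best = -1;
      for (size_t ci = 0; ci < cands.size(); ci++) {
        double e_new = res_env_energy(*S, p.r, cands[ci].code, cands[ci].scX,
                                      cands[ci].chi.empty()
                                          ? 0 : cands[ci].chi.data()) +
                       ref[cands[ci].code];
        if (e_new < e_best - 1e-12) { e_best = e_new; best = (int)ci; }
      }
      if (best >= 0) { apply(p.r, cands[best]); changed = true; }
    }
    if (!changed) break;
  }
  Scores sc = score_all(*S, S->X, 0);
  return List::create(_["total"] = total_of(*S, sc));
}
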