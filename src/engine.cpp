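// Core simulation engine: force-shifted tabulated-form pair interactions,
// harmonic bonds/angles, Verlet/cell neighbor list, steepest-descent
// minimization and a BAOAB-split Langevin integrator with semi-isotropic
// Berendsen pressure coupling in the membrane (xy) plane.
//
// Unit system: nm, ps, amu, kJ/mol (1 kJ/mol = 1 amu nm^2/ps^2), K, bar.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.0083144621;      // kJ/mol/K
static const double PRESS_UNIT = 16.6054;   // kJ/mol/nm^3 -> bar

struct Term {
  double c;      // coefficient of c / r^alpha (sign carries attraction)
  double alpha;  // interaction power
  double A, B;   // shift polynomial coefficients (per-term, own alpha)
  double Cshift; // potential offset for r < r1 so that V(rc) = 0
  // precomputed combinations for the force loop
  double ac;     // alpha * c
  double cA, cB;       // alpha * c * A, alpha * c * B
  double cA3, cB4;     // alpha * c * A / 3, alpha * c * B / 4
};

struct PairClass {
  bool active = false;
  double r1 = 0.0, rc = 0.0, rc2 = 0.0;
  std::vector<Term> terms;
};

// Shift coefficients for one power-law term; dialect without the leading
// alpha factor (it is reinstated in the force expression below).
static inline void shift_AB(double alpha, double r1, double rc,
                            double &A, double &B) {
  double d = rc - r1;
  double denom = std::pow(rc, alpha + 2.0);
  A = -((alpha + 4.0) * rc - (alpha + 1.0) * r1) / (denom * d * d);
  B = ((alpha + 3.0) * rc - (alpha + 1.0) * r1) / (denom * d * d * d);
}

// r^-alpha from precomputed 1/r^2 and 1/r, specialized for the powers the
// model uses (6, 0.5, 12); generic std::pow fallback for anything else
static inline double inv_pow2(double r, double inv2, double invr,
                              double alpha) {
  if (alpha == 6.0) return inv2 * inv2 * inv2;
  if (alpha == 0.5) return std::sqrt(invr);
  if (alpha == 12.0) {
    double i6 = inv2 * inv2 * inv2;
    return i6 * i6;
  }
  return std::pow(r, -alpha);
}

// Evaluate one shifted term at distance r (with 1/r and 1/r^2 shared across
// terms): adds energy to *u and f/r (f = -dV/dr, positive = repulsive,
// divided by r for direct use with the displacement vector) to *s.
static inline void eval_term(const Term &t, double r, double invr,
                             double inv2, double r1, double rc,
                             double *u, double *s) {
  if (r >= rc) return;
  double inv_ra = inv_pow2(r, inv2, invr, t.alpha);
  if (r < r1) {
    *u += t.c * inv_ra + t.Cshift;
    *s += t.ac * inv_ra * inv2;
  } else {
    double x = r - r1;
    double x2 = x * x, x3 = x2 * x;
    *u += t.c * inv_ra + t.Cshift - t.cA3 * x3 - t.cB4 * x3 * x;
    *s += t.ac * inv_ra * inv2 + (t.cA * x2 + t.cB * x3) * invr;
  }
}

struct Topology {
  int n;
  std::vector<int> type;   // 0-based type index
  std::vector<int> mol;    // molecule id, 0-based
  std::vector<double> mass;
  int ntypes;
  std::vector<PairClass> pc;     // ntypes*ntypes lookup
  // bonds: i, j, r0, k ; angles: i, j, k(vertex is j), theta0, kang
  std::vector<std::array<double,4>> bonds;
  std::vector<std::array<double,5>> angles;
  std::vector<int64_t> excl;     // sorted i*n+j keys (i < j), nonbonded skips
  double max_rc = 0.0;

  bool excluded(int i, int j) const {
    if (i > j) std::swap(i, j);
    int64_t key = (int64_t)i * n + j;
    return std::binary_search(excl.begin(), excl.end(), key);
  }
};

static Topology make_topology(const IntegerVector &type,
                              const IntegerVector &mol,
                              const NumericVector &mass,
                              int ntypes,
                              const List &pairdefs,
                              const NumericMatrix &bonds,
                              const NumericMatrix &angles,
                              const NumericMatrix &exclusions) {
  Topology top;
  top.n = type.size();
  top.type.resize(top.n);
  for (int i = 0; i < top.n; ++i) top.type[i] = type[i] - 1;  // R is 1-based
  top.mol.assign(mol.begin(), mol.end());
  top.mass.assign(mass.begin(), mass.end());
  top.ntypes = ntypes;
  top.pc.resize(ntypes * ntypes);
  for (int k = 0; k < pairdefs.size(); ++k) {
    List pd = pairdefs[k];
    int t1 = as<int>(pd["t1"]) - 1, t2 = as<int>(pd["t2"]) - 1;
    PairClass cls;
    cls.active = true;
    cls.r1 = as<double>(pd["r1"]);
    cls.rc = as<double>(pd["rc"]);
    cls.rc2 = cls.rc * cls.rc;
    // shift dialect: "gromacs" scales the polynomial correction of each
    // term by its power alpha (the manual's convention); "literal" applies
    // the printed A, B without the alpha factor
    bool literal = pd.containsElementNamed("dialect") &&
                   as<std::string>(pd["dialect"]) == "literal";
    NumericMatrix tm = pd["terms"];
    for (int i = 0; i < tm.nrow(); ++i) {
      Term t;
      t.c = tm(i, 0);
      t.alpha = tm(i, 1);
      shift_AB(t.alpha, cls.r1, cls.rc, t.A, t.B);
      double d = cls.rc - cls.r1;
      double pa = literal ? 1.0 : t.alpha;   // polynomial prefactor
      t.Cshift = -t.c * std::pow(cls.rc, -t.alpha) +
                 t.c * pa * (t.A / 3.0 * d * d * d + t.B / 4.0 * d * d * d * d);
      t.ac = t.alpha * t.c;
      t.cA = t.c * pa * t.A;
      t.cB = t.c * pa * t.B;
      t.cA3 = t.c * pa * t.A / 3.0;
      t.cB4 = t.c * pa * t.B / 4.0;
      cls.terms.push_back(t);
    }
    top.max_rc = std::max(top.max_rc, cls.rc);
    top.pc[t1 * ntypes + t2] = cls;
    top.pc[t2 * ntypes + t1] = cls;
  }
  for (int i = 0; i < bonds.nrow(); ++i)
    top.bonds.push_back({bonds(i,0) - 1, bonds(i,1) - 1, bonds(i,2), bonds(i,3)});
  for (int i = 0; i < angles.nrow(); ++i)
    top.angles.push_back({angles(i,0) - 1, angles(i,1) - 1, angles(i,2) - 1,
                          angles(i,3), angles(i,4)});
  top.excl.reserve(exclusions.nrow());
  for (int k = 0; k < exclusions.nrow(); ++k) {
    int i = (int)exclusions(k, 0) - 1, j = (int)exclusions(k, 1) - 1;
    if (i > j) std::swap(i, j);
    top.excl.push_back((int64_t)i * top.n + j);
  }
  std::sort(top.excl.begin(), top.excl.end());
  return top;
}

static inline double min_image(double dx, double L) {
  return dx - L * std::nearbyint(dx / L);
}


// ---- neighbor list -------------------------------------------------------

// Verlet pair list with per-pair periodic shift multipliers frozen at build
// time; particles move less than skin/2 between rebuilds, so the image
// choice stays valid (also under barostat scaling, which scales positions
// and box lengths together).
struct PairEntry {
  int i, j;
  int cls;                    // pair-class index into Topology::pc
  signed char mx, my, mz;     // image shift multipliers
};

struct NeighborList {
  std::vector<PairEntry> pairs;
  std::vector<double> ref;   // positions at build time
  double skin = 0.5;

  void add_pair(const std::vector<double> &x, const Topology &top,
                const double *box, double cut2, int i, int j) {
    if (top.excluded(i, j)) return;
    double dx = x[3*i] - x[3*j];
    double dy = x[3*i+1] - x[3*j+1];
    double dz = x[3*i+2] - x[3*j+2];
    int mx = (int)std::nearbyint(dx / box[0]);
    int my = (int)std::nearbyint(dy / box[1]);
    int mz = (int)std::nearbyint(dz / box[2]);
    dx -= mx * box[0]; dy -= my * box[1]; dz -= mz * box[2];
    if (dx*dx + dy*dy + dz*dz < cut2) {
      PairEntry e;
      e.i = i; e.j = j;
      e.cls = top.type[i] * top.ntypes + top.type[j];
      e.mx = (signed char)(-mx); e.my = (signed char)(-my);
      e.mz = (signed char)(-mz);
      pairs.push_back(e);
    }
  }

  void build(const std::vector<double> &x, const Topology &top,
             const double *box) {
    pairs.clear();
    int n = top.n;
    double cut = top.max_rc + skin, cut2 = cut * cut;
    int ncx = (int)std::floor(box[0] / cut);
    int ncy = (int)std::floor(box[1] / cut);
    int ncz = (int)std::floor(box[2] / cut);
    if (ncx >= 3 && ncy >= 3 && ncz >= 3) {
      int ncell = ncx * ncy * ncz;
      std::vector<std::vector<int>> cells(ncell);
      for (int i = 0; i < n; ++i) {
        double xw = x[3*i]   - box[0] * std::floor(x[3*i]   / box[0]);
        double yw = x[3*i+1] - box[1] * std::floor(x[3*i+1] / box[1]);
        double zw = x[3*i+2] - box[2] * std::floor(x[3*i+2] / box[2]);
        int cx = std::min((int)(xw / box[0] * ncx), ncx - 1);
        int cy = std::min((int)(yw / box[1] * ncy), ncy - 1);
        int cz = std::min((int)(zw / box[2] * ncz), ncz - 1);
        cells[(cx * ncy + cy) * ncz + cz].push_back(i);
      }
      // half stencil: every cell pair visited once (no {o, -o} duplicates,
      // and with >= 3 cells per dimension no periodic aliasing)
      static const int half[13][3] = {
        {1,0,0}, {-1,1,0}, {0,1,0}, {1,1,0}, {-1,-1,1}, {0,-1,1}, {1,-1,1},
        {-1,0,1}, {0,0,1}, {1,0,1}, {-1,1,1}, {0,1,1}, {1,1,1}};
      for (int cx = 0; cx < ncx; ++cx)
      for (int cy = 0; cy < ncy; ++cy)
      for (int cz = 0; cz < ncz; ++cz) {
        const std::vector<int> &ca = cells[(cx * ncy + cy) * ncz + cz];
        if (ca.empty()) continue;
        for (size_t a = 0; a + 1 < ca.size(); ++a)
          for (size_t b = a + 1; b < ca.size(); ++b)
            add_pair(x, top, box, cut2, ca[a], ca[b]);
        for (auto &o : half) {
          int dx = (cx + o[0] + ncx) % ncx;
          int dy = (cy + o[1] + ncy) % ncy;
          int dz = (cz + o[2] + ncz) % ncz;
          const std::vector<int> &cb = cells[(dx * ncy + dy) * ncz + dz];
          for (int i : ca)
            for (int j : cb)
              add_pair(x, top, box, cut2, i, j);
        }
      }
    } else {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          add_pair(x, top, box, cut2, i, j);
    }
    ref = x;
  }

  bool stale(const std::vector<double> &x) const {
    double lim = 0.25 * skin * skin;   // (skin/2)^2
    for (size_t i = 0; i < x.size(); i += 3) {
      double dx = x[i] - ref[i], dy = x[i+1] - ref[i+1], dz = x[i+2] - ref[i+2];
      if (dx*dx + dy*dy + dz*dz > lim) return true;
    }
    return false;
  }
};

// ---- force evaluation ----------------------------------------------------

struct ForceResult {
  double epot;
  double virial[3];
};

static ForceResult compute_forces_core(const std::vector<double> &x,
                                       const Topology &top,
                                       const double *box,
                                       const std::vector<PairEntry> &pairs,
                                       std::vector<double> &f) {
  ForceResult res;
  res.epot = 0.0;
  res.virial[0] = res.virial[1] = res.virial[2] = 0.0;
  std::fill(f.begin(), f.end(), 0.0);

  for (const PairEntry &pr : pairs) {
    const PairClass &cls = top.pc[pr.cls];
    if (!cls.active) continue;
    const int i = pr.i, j = pr.j;
    double dx = x[3*i]   - x[3*j]   + pr.mx * box[0];
    double dy = x[3*i+1] - x[3*j+1] + pr.my * box[1];
    double dz = x[3*i+2] - x[3*j+2] + pr.mz * box[2];
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 >= cls.rc2) continue;
    if (r2 < 1e-12) stop("singular configuration: beads %d and %d overlap", i + 1, j + 1);
    double inv2 = 1.0 / r2;
    double r = std::sqrt(r2);
    double invr = 1.0 / r;
    double u = 0.0, s = 0.0;
    for (auto &t : cls.terms)
      eval_term(t, r, invr, inv2, cls.r1, cls.rc, &u, &s);
    res.epot += u;
    f[3*i]   += s * dx; f[3*j]   -= s * dx;
    f[3*i+1] += s * dy; f[3*j+1] -= s * dy;
    f[3*i+2] += s * dz; f[3*j+2] -= s * dz;
    res.virial[0] += s * dx * dx;
    res.virial[1] += s * dy * dy;
    res.virial[2] += s * dz * dz;
  }

  for (auto &b : top.bonds) {
    int i = (int)b[0], j = (int)b[1];
    double r0 = b[2], k = b[3];
    double dx = min_image(x[3*i] - x[3*j], box[0]);
    double dy = min_image(x[3*i+1] - x[3*j+1], box[1]);
    double dz = min_image(x[3*i+2] - x[3*j+2], box[2]);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (r < 1e-9) stop("degenerate bond length");
    res.epot += 0.5 * k * (r - r0) * (r - r0);
    double s = -k * (r - r0) / r;
    f[3*i]   += s * dx; f[3*j]   -= s * dx;
    f[3*i+1] += s * dy; f[3*j+1] -= s * dy;
    f[3*i+2] += s * dz; f[3*j+2] -= s * dz;
    res.virial[0] += s * dx * dx;
    res.virial[1] += s * dy * dy;
    res.virial[2] += s * dz * dz;
  }

  for (auto &a : top.angles) {
    int i = (int)a[0], jv = (int)a[1], k = (int)a[2];
    double th0 = a[3], ka = a[4];
    double r1x = min_image(x[3*i] - x[3*jv], box[0]);
    double r1y = min_image(x[3*i+1] - x[3*jv+1], box[1]);
    double r1z = min_image(x[3*i+2] - x[3*jv+2], box[2]);
    double r2x = min_image(x[3*k] - x[3*jv], box[0]);
    double r2y = min_image(x[3*k+1] - x[3*jv+1], box[1]);
    double r2z = min_image(x[3*k+2] - x[3*jv+2], box[2]);
    double n1 = std::sqrt(r1x*r1x + r1y*r1y + r1z*r1z);
    double n2 = std::sqrt(r2x*r2x + r2y*r2y + r2z*r2z);
    double ct = (r1x*r2x + r1y*r2y + r1z*r2z) / (n1 * n2);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double st = std::sqrt(std::max(1.0 - ct * ct, 1e-12));
    res.epot += 0.5 * ka * (th - th0) * (th - th0);
    // F_i = -dV/dtheta * dtheta/dr_i = (dV/dtheta / sin(theta)) * d(cos)/dr_i
    double dVdth = ka * (th - th0);
    double coef = dVdth / st;
    // dtheta/dr derivatives of cos(theta)
    double f1x = coef * (r2x / (n1 * n2) - ct * r1x / (n1 * n1));
    double f1y = coef * (r2y / (n1 * n2) - ct * r1y / (n1 * n1));
    double f1z = coef * (r2z / (n1 * n2) - ct * r1z / (n1 * n1));
    double f2x = coef * (r1x / (n1 * n2) - ct * r2x / (n2 * n2));
    double f2y = coef * (r1y / (n1 * n2) - ct * r2y / (n2 * n2));
    double f2z = coef * (r1z / (n1 * n2) - ct * r2z / (n2 * n2));
    f[3*i]    += f1x; f[3*i+1]  += f1y; f[3*i+2]  += f1z;
    f[3*k]    += f2x; f[3*k+1]  += f2y; f[3*k+2]  += f2z;
    f[3*jv]   -= f1x + f2x;
    f[3*jv+1] -= f1y + f2y;
    f[3*jv+2] -= f1z + f2z;
    res.virial[0] += f1x * r1x + f2x * r2x;
    res.virial[1] += f1y * r1y + f2y * r2y;
    res.virial[2] += f1z * r1z + f2z * r2z;
  }
  return res;
}

// all-pairs pair list (no neighbor list): used as internal brute-force path
static std::vector<PairEntry> all_pairs(const std::vector<double> &x,
                                        const Topology &top,
                                        const double *box) {
  std::vector<PairEntry> p;
  for (int i = 0; i < top.n; ++i)
    for (int j = i + 1; j < top.n; ++j) {
      if (top.excluded(i, j)) continue;
      PairEntry e;
      e.i = i; e.j = j;
      e.cls = top.type[i] * top.ntypes + top.type[j];
      e.mx = (signed char)(-(int)std::nearbyint((x[3*i] - x[3*j]) / box[0]));
      e.my = (signed char)(-(int)std::nearbyint((x[3*i+1] - x[3*j+1]) / box[1]));
      e.mz = (signed char)(-(int)std::nearbyint((x[3*i+2] - x[3*j+2]) / box[2]));
      p.push_back(e);
    }
  return p;
}

// [[Rcpp::export]]
List tl_compute_forces(NumericMatrix pos, IntegerVector type, IntegerVector mol,
                       NumericVector mass, int ntypes, List pairdefs,
                       NumericMatrix bonds, NumericMatrix angles,
                       NumericMatrix exclusions,
                       NumericVector box, bool brute = false) {
  Topology top = make_topology(type, mol, mass, ntypes, pairdefs, bonds, angles,
                               exclusions);
  int n = top.n;
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = pos(i, d);
  std::vector<PairEntry> pairs;
  if (brute) {
    pairs = all_pairs(x, top, box.begin());
  } else {
    NeighborList nl;
    nl.build(x, top, box.begin());
    pairs = nl.pairs;
  }
  ForceResult res = compute_forces_core(x, top, box.begin(), pairs, f);
  NumericMatrix fm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) fm(i, d) = f[3*i+d];
  return List::create(_["forces"] = fm, _["epot"] = res.epot,
                      _["virial"] = NumericVector::create(res.virial[0],
                                                          res.virial[1],
                                                          res.virial[2]));
}

// [[Rcpp::export]]
List tl_minimize(NumericMatrix pos, IntegerVector type, IntegerVector mol,
                 NumericVector mass, int ntypes, List pairdefs,
                 NumericMatrix bonds, NumericMatrix angles,
                 NumericMatrix exclusions, NumericVector box,
                 int max_steps = 1000, double f_tol = 10.0, double h0 = 0.01) {
  Topology top = make_topology(type, mol, mass, ntypes, pairdefs, bonds, angles,
                               exclusions);
  int n = top.n;
  std::vector<double> x(3 * n), f(3 * n), xt(3 * n), ft(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = pos(i, d);
  NeighborList nl;
  nl.build(x, top, box.begin());
  ForceResult res = compute_forces_core(x, top, box.begin(), nl.pairs, f);
  double h = h0;
  int it = 0;
  double fmax = 0.0;
  for (it = 0; it < max_steps; ++it) {
    fmax = 0.0;
    for (double v : f) fmax = std::max(fmax, std::fabs(v));
    if (fmax < f_tol) break;
    for (int i = 0; i < 3 * n; ++i) xt[i] = x[i] + h * f[i] / fmax;
    nl.build(xt, top, box.begin());
    ForceResult rt = compute_forces_core(xt, top, box.begin(), nl.pairs, ft);
    if (std::isfinite(rt.epot) && rt.epot < res.epot) {
      x = xt; f = ft; res = rt;
      h = std::min(h * 1.2, 0.05);
    } else {
      h *= 0.5;
      if (h < 1e-10) break;
      nl.build(x, top, box.begin());
    }
  }
  NumericMatrix pm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) pm(i, d) = x[3*i+d];
  return List::create(_["pos"] = pm, _["epot"] = res.epot,
                      _["iterations"] = it, _["fmax"] = fmax);
}

// wrap coordinates so that each molecule's center of mass is inside the box
static void wrap_molecules(std::vector<double> &x, const Topology &top,
                           const double *box) {
  int nmol = 0;
  for (int m : top.mol) nmol = std::max(nmol, m + 1);
  std::vector<double> cx(nmol, 0.0), cy(nmol, 0.0), cz(nmol, 0.0), cm(nmol, 0.0);
  for (int i = 0; i < top.n; ++i) {
    int m = top.mol[i];
    cx[m] += top.mass[i] * x[3*i];
    cy[m] += top.mass[i] * x[3*i+1];
    cz[m] += top.mass[i] * x[3*i+2];
    cm[m] += top.mass[i];
  }
  for (int m = 0; m < nmol; ++m) {
    cx[m] /= cm[m]; cy[m] /= cm[m]; cz[m] /= cm[m];
  }
  for (int i = 0; i < top.n; ++i) {
    int m = top.mol[i];
    x[3*i]   -= box[0] * std::floor(cx[m] / box[0]);
    x[3*i+1] -= box[1] * std::floor(cy[m] / box[1]);
    x[3*i+2] -= box[2] * std::floor(cz[m] / box[2]);
  }
}

// [[Rcpp::export]]
List tl_run_ld(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
               IntegerVector mol, NumericVector mass, int ntypes, List pairdefs,
               NumericMatrix bonds, NumericMatrix angles,
               NumericMatrix exclusions, NumericVector box0,
               double dt, double temperature, double gamma, int n_steps,
               int report_interval, int snapshot_interval, int seed,
               int barostat, double P_ref, double kappa_xy, double tau_p,
               int mc_interval, double mc_delta) {
  Topology top = make_topology(type, mol, mass, ntypes, pairdefs, bonds, angles,
                               exclusions);
  int n = top.n;
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  double box[3] = {box0[0], box0[1], box0[2]};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      x[3*i+d] = pos(i, d);
      v[3*i+d] = vel(i, d);
    }

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  double c1 = std::exp(-gamma * dt);
  std::vector<double> c2(n);
  for (int i = 0; i < n; ++i)
    c2[i] = std::sqrt(KB * temperature / top.mass[i] * (1.0 - c1 * c1));

  NeighborList nl;
  nl.build(x, top, box);
  ForceResult res = compute_forces_core(x, top, box, nl.pairs, f);

  int n_reports = (report_interval > 0) ? n_steps / report_interval : 0;
  NumericMatrix frames(n_reports, 10);
  List snapshots;
  int rep = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i) {
      double im = dt * 0.5 / top.mass[i];
      v[3*i]   += im * f[3*i];
      v[3*i+1] += im * f[3*i+1];
      v[3*i+2] += im * f[3*i+2];
    }
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O: Ornstein-Uhlenbeck velocity update (exact)
    if (gamma > 0) {
      for (int i = 0; i < n; ++i) {
        v[3*i]   = c1 * v[3*i]   + c2[i] * gauss(rng);
        v[3*i+1] = c1 * v[3*i+1] + c2[i] * gauss(rng);
        v[3*i+2] = c1 * v[3*i+2] + c2[i] * gauss(rng);
      }
    }
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];

    if (nl.stale(x)) {
      wrap_molecules(x, top, box);
      nl.build(x, top, box);
    }
    res = compute_forces_core(x, top, box, nl.pairs, f);
    // B: half kick
    for (int i = 0; i < n; ++i) {
      double im = dt * 0.5 / top.mass[i];
      v[3*i]   += im * f[3*i];
      v[3*i+1] += im * f[3*i+1];
      v[3*i+2] += im * f[3*i+2];
    }

    // instantaneous kinetic tensor diagonal and pressure
    double ke[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i) {
      ke[0] += 0.5 * top.mass[i] * v[3*i]   * v[3*i];
      ke[1] += 0.5 * top.mass[i] * v[3*i+1] * v[3*i+1];
      ke[2] += 0.5 * top.mass[i] * v[3*i+2] * v[3*i+2];
    }
    double vol = box[0] * box[1] * box[2];
    double P[3];
    for (int d = 0; d < 3; ++d)
      P[d] = (2.0 * ke[d] + res.virial[d]) / vol * PRESS_UNIT;

    if (barostat == 1) {
      // Berendsen: joint first-order relaxation of the lateral box area
      double P_lat = 0.5 * (P[0] + P[1]);
      double mu2 = 1.0 - kappa_xy * dt / tau_p * (P_ref - P_lat);
      double mu = std::sqrt(std::max(mu2, 0.0));
      if (mu < 0.98) mu = 0.98;
      if (mu > 1.02) mu = 1.02;
      box[0] *= mu; box[1] *= mu;
      for (int i = 0; i < n; ++i) {
        x[3*i]   *= mu;
        x[3*i+1] *= mu;
      }
    } else if (barostat == 2 && step % mc_interval == 0) {
      // Monte Carlo area moves: canonical lateral-area ensemble, so box
      // fluctuations obey equilibrium statistics (unlike Berendsen's
      // deterministically damped relaxation)
      std::uniform_real_distribution<double> unif(0.0, 1.0);
      double dlnA = mc_delta * (2.0 * unif(rng) - 1.0);
      double mu = std::exp(0.5 * dlnA);
      double A_old = box[0] * box[1];
      double box_new[3] = {box[0] * mu, box[1] * mu, box[2]};
      std::vector<double> xn = x;
      for (int i = 0; i < n; ++i) { xn[3*i] *= mu; xn[3*i+1] *= mu; }
      NeighborList nlt;
      nlt.build(xn, top, box_new);
      std::vector<double> ft(3 * n);
      ForceResult rt = compute_forces_core(xn, top, box_new, nlt.pairs, ft);
      double dA = A_old * (std::exp(dlnA) - 1.0);
      double work = P_ref * box[2] * dA / PRESS_UNIT;   // bar nm^3 -> kJ/mol
      double beta = 1.0 / (KB * temperature);
      double arg = -beta * (rt.epot - res.epot + work) + n * dlnA;
      if (std::isfinite(rt.epot) && std::log(unif(rng) + 1e-300) < arg) {
        x = std::move(xn); f = std::move(ft); res = rt;
        box[0] = box_new[0]; box[1] = box_new[1];
        nl = std::move(nlt);
      }
    }

    if (report_interval > 0 && step % report_interval == 0) {
      double ektot = ke[0] + ke[1] + ke[2];
      if (!std::isfinite(res.epot) || !std::isfinite(ektot))
        stop("simulation blew up at step %d (non-finite energy)", step);
      frames(rep, 0) = step;
      frames(rep, 1) = step * dt;
      frames(rep, 2) = box[0];
      frames(rep, 3) = box[1];
      frames(rep, 4) = box[2];
      frames(rep, 5) = res.epot;
      frames(rep, 6) = ektot;
      frames(rep, 7) = P[0];
      frames(rep, 8) = P[1];
      frames(rep, 9) = P[2];
      ++rep;
    }
    if (snapshot_interval > 0 && step % snapshot_interval == 0) {
      std::vector<double> xw = x;
      wrap_molecules(xw, top, box);
      NumericMatrix snap(n, 3);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) snap(i, d) = xw[3*i+d];
      snapshots.push_back(snap);
    }
  }

  std::vector<double> xw = x;
  wrap_molecules(xw, top, box);
  NumericMatrix pm(n, 3), vm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      pm(i, d) = xw[3*i+d];
      vm(i, d) = v[3*i+d];
    }
  return List::create(_["frames"] = frames, _["snapshots"] = snapshots,
                      _["pos"] = pm, _["vel"] = vm,
                      _["box"] = NumericVector::create(box[0], box[1], box[2]));
}

// Maxwell-Boltzmann velocities from the engine's own RNG (deterministic per seed)
// [[Rcpp::export]]
NumericMatrix tl_maxwell(NumericVector mass, double temperature, int seed) {
  int n = mass.size();
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  NumericMatrix v(n, 3);
  for (int i = 0; i < n; ++i) {
    double s = std::sqrt(KB * temperature / mass[i]);
    for (int d = 0; d < 3; ++d) v(i, d) = s * gauss(rng);
  }
  return v;
}
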