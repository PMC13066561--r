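// Energy/force kernels and Langevin (BAOAB) integrator for the
// coarse-grained chromatosome model: harmonic bonded terms, tabulated
// flexible-local terms on disordered stretches, 12-10 Go contacts,
// Morse base pairing / stacking / hydrogen bonds, Ashbaugh-Hatch (HPS)
// pairs, excluded volume, and Debye-Hueckel electrostatics with the
// pair-context phosphate charge (-0.6 e DNA-DNA, -1.0 e protein-DNA).
//
// Units: length Angstrom, energy kcal/mol, mass amu.  The derived time
// unit sqrt(amu A^2 / (kcal/mol)) ~ 48.9 fs is the "CG time unit".

#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t h) {
  // strictly inside (0,1)
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// Counter-based Gaussian noise: a pure function of (seed, step, index),
// so restarts from any step reproduce the stream exactly.
static inline double gauss_at(uint64_t seed, uint64_t step, uint64_t idx) {
  uint64_t h1 = splitmix64(splitmix64(seed ^ 0xA5A5A5A5DEADBEEFULL) ^
                           splitmix64(step + 0x1234567ULL) ^
                           splitmix64(idx * 0x9E3779B97F4A7C15ULL + 11ULL));
  uint64_t h2 = splitmix64(h1 ^ 0x0123456789ABCDEFULL);
  double u1 = u01(h1), u2 = u01(h2);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

static inline uint64_t pairkey(int i, int j) {
  int a = i < j ? i : j, b = i < j ? j : i;
  return (static_cast<uint64_t>(a) << 32) | static_cast<uint64_t>(b);
}

struct Model {
  int n;
  std::vector<int> is_dna, is_phos, disordered;
  std::vector<double> charge, hl, hs, mass;
  NumericMatrix bonds, angles, dihedrals, contacts, morse_bp, morse_st, morse_hb;
  IntegerMatrix fang, fdih;
  NumericMatrix ang_tab, dih_tab;
  std::unordered_set<uint64_t> excl12; // excluded from all nonbonded
  std::unordered_set<uint64_t> exclev; // excluded from EV + HPS only
  double kcoul, eps_r, lambda_D, q_pd, q_pp;
  double cut_elec, cut_other, ev_eps, ev_sigma, hps_eps;
};

static Model build_model(List ff) {
  Model m;
  IntegerVector isd = ff["is_dna"], isp = ff["is_phos"], dis = ff["disordered"];
  NumericVector q = ff["charge"], hl = ff["hps_lambda"], hs = ff["hps_sigma"],
                mass = ff["mass"];
  m.n = isd.size();
  m.is_dna.assign(isd.begin(), isd.end());
  m.is_phos.assign(isp.begin(), isp.end());
  m.disordered.assign(dis.begin(), dis.end());
  m.charge.assign(q.begin(), q.end());
  m.hl.assign(hl.begin(), hl.end());
  m.hs.assign(hs.begin(), hs.end());
  m.mass.assign(mass.begin(), mass.end());
  m.bonds = as<NumericMatrix>(ff["bonds"]);
  m.angles = as<NumericMatrix>(ff["angles"]);
  m.dihedrals = as<NumericMatrix>(ff["dihedrals"]);
  m.contacts = as<NumericMatrix>(ff["contacts"]);
  m.morse_bp = as<NumericMatrix>(ff["morse_bp"]);
  m.morse_st = as<NumericMatrix>(ff["morse_st"]);
  m.morse_hb = as<NumericMatrix>(ff["morse_hb"]);
  m.fang = as<IntegerMatrix>(ff["flex_angles"]);
  m.fdih = as<IntegerMatrix>(ff["flex_dihedrals"]);
  m.ang_tab = as<NumericMatrix>(ff["angle_tables"]);
  m.dih_tab = as<NumericMatrix>(ff["dihedral_tables"]);
  IntegerVector e12i = ff["excl12_i"], e12j = ff["excl12_j"];
  IntegerVector eevi = ff["exclev_i"], eevj = ff["exclev_j"];
  for (int k = 0; k < e12i.size(); ++k)
    m.excl12.insert(pairkey(e12i[k] - 1, e12j[k] - 1));
  for (int k = 0; k < eevi.size(); ++k)
    m.exclev.insert(pairkey(eevi[k] - 1, eevj[k] - 1));
  List ctx = ff["ctx"];
  m.kcoul = as<double>(ctx["kcoul"]);
  m.eps_r = as<double>(ctx["eps_r"]);
  m.lambda_D = as<double>(ctx["lambda_D"]);
  m.q_pd = as<double>(ctx["q_phos_dna"]);
  m.q_pp = as<double>(ctx["q_phos_protein"]);
  m.cut_elec = as<double>(ctx["cutoff_elec"]);
  m.cut_other = as<double>(ctx["cutoff_other"]);
  m.ev_eps = as<double>(ctx["ev_eps"]);
  m.ev_sigma = as<double>(ctx["ev_sigma"]);
  m.hps_eps = as<double>(ctx["hps_eps"]);
  return m;
}

struct Vec3 { double x, y, z; };
static inline Vec3 vsub(const double* a, const double* b) {
  Vec3 v; v.x = a[0] - b[0]; v.y = a[1] - b[1]; v.z = a[2] - b[2]; return v;
}
static inline double vdot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 vcross(const Vec3& a, const Vec3& b) {
  Vec3 v; v.x = a.y * b.z - a.z * b.y; v.y = a.z * b.x - a.x * b.z;
  v.z = a.x * b.y - a.y * b.x; return v;
}
static inline double vnorm(const Vec3& a) { return std::sqrt(vdot(a, a)); }

// Catmull-Rom interpolation on a uniform grid; returns value, fills deriv.
// periodic: wraps node indices; otherwise end nodes are clamped.
static double interp_table(const double* y, int nn, double x0, double x1,
                           bool periodic, double x, double* dydx) {
  int ncell = periodic ? nn : (nn - 1);
  double h = (x1 - x0) / ncell;
  double t = (x - x0) / h;
  int k = (int)std::floor(t);
  if (periodic) {
    k = ((k % ncell) + ncell) % ncell;
  } else {
    if (k < 0) k = 0;
    if (k > ncell - 1) k = ncell - 1;
  }
  double u = t - std::floor(t);
  if (!periodic) u = (x - (x0 + k * h)) / h;
  auto node = [&](int idx) -> double {
    if (periodic) return y[((idx % nn) + nn) % nn];
    if (idx < 0) idx = 0;
    if (idx > nn - 1) idx = nn - 1;
    return y[idx];
  };
  double y0 = node(k - 1), y1 = node(k), y2 = node(k + 1), y3 = node(k + 2);
  double a = 2.0 * y1;
  double b = -y0 + y2;
  double c = 2.0 * y0 - 5.0 * y1 + 4.0 * y2 - y3;
  double d = -y0 + 3.0 * y1 - 3.0 * y2 + y3;
  double val = 0.5 * (a + b * u + c * u * u + d * u * u * u);
  *dydx = 0.5 * (b + 2.0 * c * u + 3.0 * d * u * u) / h;
  return val;
}

// angle between beads i-j-k and its gradient
static double angle_and_grad(const double* ri, const double* rj,
                             const double* rk, Vec3* gi, Vec3* gj, Vec3* gk) {
  Vec3 a = vsub(ri, rj), b = vsub(rk, rj);
  double la = vnorm(a), lb = vnorm(b);
  double ct = vdot(a, b) / (la * lb);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  double theta = std::acos(ct);
  double st = std::sqrt(1.0 - ct * ct);
  if (st < 1e-8) st = 1e-8;
  Vec3 ua{a.x / la, a.y / la, a.z / la}, ub{b.x / lb, b.y / lb, b.z / lb};
  gi->x = (ct * ua.x - ub.x) / (la * st);
  gi->y = (ct * ua.y - ub.y) / (la * st);
  gi->z = (ct * ua.z - ub.z) / (la * st);
  gk->x = (ct * ub.x - ua.x) / (lb * st);
  gk->y = (ct * ub.y - ua.y) / (lb * st);
  gk->z = (ct * ub.z - ua.z) / (lb * st);
  gj->x = -gi->x - gk->x; gj->y = -gi->y - gk->y; gj->z = -gi->z - gk->z;
  return theta;
}

// dihedral i-j-k-l and its gradient (standard formulation)
static double dihedral_and_grad(const double* ri, const double* rj,
                                const double* rk, const double* rl,
                                Vec3* g1, Vec3* g2, Vec3* g3, Vec3* g4) {
  Vec3 b1 = vsub(rj, ri), b2 = vsub(rk, rj), b3 = vsub(rl, rk);
  Vec3 n1 = vcross(b1, b2), n2 = vcross(b2, b3);
  double lb2 = vnorm(b2);
  Vec3 m1 = vcross(n1, b2);
  double x = vdot(n1, n2);
  double y = vdot(m1, n2) / lb2;
  double phi = std::atan2(y, x);
  double n1sq = vdot(n1, n1), n2sq = vdot(n2, n2);
  if (n1sq < 1e-12) n1sq = 1e-12;
  if (n2sq < 1e-12) n2sq = 1e-12;
  double f1 = lb2 / n1sq, f4 = -lb2 / n2sq;
  g1->x = f1 * n1.x; g1->y = f1 * n1.y; g1->z = f1 * n1.z;
  g4->x = f4 * n2.x; g4->y = f4 * n2.y; g4->z = f4 * n2.z;
  double c12 = vdot(b1, b2) / (lb2 * lb2);
  double c32 = vdot(b3, b2) / (lb2 * lb2);
  g2->x = -(1.0 + c12) * g1->x + c32 * g4->x;
  g2->y = -(1.0 + c12) * g1->y + c32 * g4->y;
  g2->z = -(1.0 + c12) * g1->z + c32 * g4->z;
  g3->x = c12 * g1->x - (1.0 + c32) * g4->x;
  g3->y = c12 * g1->y - (1.0 + c32) * g4->y;
  g3->z = c12 * g1->z - (1.0 + c32) * g4->z;
  return phi;
}

// pair list entry: i, j, flag (1 = skip EV/HPS, specific term present)
struct Pair { int i, j, flag; };

// range2_elec / range2_other are squared list ranges (cutoff + skin).
// Pairs beyond the other-range are kept only when both beads can carry
// charge (they contribute nothing otherwise).
static void build_pairs(const std::vector<double>& px,
                        const std::vector<double>& py,
                        const std::vector<double>& pz,
                        const Model& m, double range2_elec,
                        double range2_other, std::vector<Pair>& out) {
  out.clear();
  int n = m.n;
  std::vector<char> chg(n);
  for (int i = 0; i < n; ++i)
    chg[i] = (m.is_phos[i] || m.charge[i] != 0.0) ? 1 : 0;
  double rmax2 = range2_elec > range2_other ? range2_elec : range2_other;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rmax2) continue;
      if (r2 >= range2_other && !(chg[i] && chg[j] && r2 < range2_elec))
        continue;
      uint64_t key = pairkey(i, j);
      if (m.excl12.count(key)) continue;
      Pair p; p.i = i; p.j = j;
      p.flag = m.exclev.count(key) ? 1 : 0;
      out.push_back(p);
    }
  }
}

// evaluate all terms; adds forces into fx/fy/fz; returns per-term energies
static void eval_all(const std::vector<double>& px,
                     const std::vector<double>& py,
                     const std::vector<double>& pz,
                     const Model& m, const std::vector<Pair>& pairs,
                     std::vector<double>& fx, std::vector<double>& fy,
                     std::vector<double>& fz, double* E /* length 11 */) {
  for (int t = 0; t < 11; ++t) E[t] = 0.0;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  const int BOND = 0, ANGLE = 1, DIH = 2, GO = 3, FLEX = 4, HPS = 5,
            EV = 6, BP = 7, STACK = 8, HB = 9, ELEC = 10;
  double pt[3], pt2[3], pt3[3], pt4[3];
  auto getp = [&](int i, double* o) { o[0] = px[i]; o[1] = py[i]; o[2] = pz[i]; };

  // bonds: U = k (r - r0)^2
  for (int b = 0; b < m.bonds.nrow(); ++b) {
    int i = (int)m.bonds(b, 0) - 1, j = (int)m.bonds(b, 1) - 1;
    double r0 = m.bonds(b, 2), k = m.bonds(b, 3);
    double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - r0;
    E[BOND] += k * dr * dr;
    double fm = -2.0 * k * dr / r;
    fx[i] += fm * dx; fy[i] += fm * dy; fz[i] += fm * dz;
    fx[j] -= fm * dx; fy[j] -= fm * dy; fz[j] -= fm * dz;
  }

  // harmonic angles: U = k (theta - theta0)^2
  for (int a = 0; a < m.angles.nrow(); ++a) {
    int i = (int)m.angles(a, 0) - 1, j = (int)m.angles(a, 1) - 1,
        k = (int)m.angles(a, 2) - 1;
    double th0 = m.angles(a, 3), ka = m.angles(a, 4);
    getp(i, pt); getp(j, pt2); getp(k, pt3);
    Vec3 gi, gj, gk;
    double th = angle_and_grad(pt, pt2, pt3, &gi, &gj, &gk);
    double dth = th - th0;
    E[ANGLE] += ka * dth * dth;
    double dU = 2.0 * ka * dth;
    fx[i] -= dU * gi.x; fy[i] -= dU * gi.y; fz[i] -= dU * gi.z;
    fx[j] -= dU * gj.x; fy[j] -= dU * gj.y; fz[j] -= dU * gj.z;
    fx[k] -= dU * gk.x; fy[k] -= dU * gk.y; fz[k] -= dU * gk.z;
  }

  // periodic dihedrals: U = k (1 - cos(phi - phi0))
  for (int d = 0; d < m.dihedrals.nrow(); ++d) {
    int i = (int)m.dihedrals(d, 0) - 1, j = (int)m.dihedrals(d, 1) - 1,
        k = (int)m.dihedrals(d, 2) - 1, l = (int)m.dihedrals(d, 3) - 1;
    double phi0 = m.dihedrals(d, 4), kd = m.dihedrals(d, 5);
    getp(i, pt); getp(j, pt2); getp(k, pt3); getp(l, pt4);
    Vec3 g1, g2, g3, g4;
    double phi = dihedral_and_grad(pt, pt2, pt3, pt4, &g1, &g2, &g3, &g4);
    E[DIH] += kd * (1.0 - std::cos(phi - phi0));
    double dU = kd * std::sin(phi - phi0);
    fx[i] -= dU * g1.x; fy[i] -= dU * g1.y; fz[i] -= dU * g1.z;
    fx[j] -= dU * g2.x; fy[j] -= dU * g2.y; fz[j] -= dU * g2.z;
    fx[k] -= dU * g3.x; fy[k] -= dU * g3.y; fz[k] -= dU * g3.z;
    fx[l] -= dU * g4.x; fy[l] -= dU * g4.y; fz[l] -= dU * g4.z;
  }

  // flexible-local angle tables (domain [0, pi], clamped)
  for (int a = 0; a < m.fang.nrow(); ++a) {
    int i = m.fang(a, 0) - 1, j = m.fang(a, 1) - 1, k = m.fang(a, 2) - 1;
    int tab = m.fang(a, 3) - 1;
    getp(i, pt); getp(j, pt2); getp(k, pt3);
    Vec3 gi, gj, gk;
    double th = angle_and_grad(pt, pt2, pt3, &gi, &gj, &gk);
    double dydx;
    NumericMatrix::ConstRow row = m.ang_tab(tab, _);
    std::vector<double> yy(row.begin(), row.end());
    double val = interp_table(yy.data(), (int)yy.size(), 0.0, M_PI, false, th, &dydx);
    E[FLEX] += val;
    fx[i] -= dydx * gi.x; fy[i] -= dydx * gi.y; fz[i] -= dydx * gi.z;
    fx[j] -= dydx * gj.x; fy[j] -= dydx * gj.y; fz[j] -= dydx * gj.z;
    fx[k] -= dydx * gk.x; fy[k] -= dydx * gk.y; fz[k] -= dydx * gk.z;
  }

  // flexible-local dihedral tables (periodic on [-pi, pi))
  for (int d = 0; d < m.fdih.nrow(); ++d) {
    int i = m.fdih(d, 0) - 1, j = m.fdih(d, 1) - 1, k = m.fdih(d, 2) - 1,
        l = m.fdih(d, 3) - 1, tab = m.fdih(d, 4) - 1;
    getp(i, pt); getp(j, pt2); getp(k, pt3); getp(l, pt4);
    Vec3 g1, g2, g3, g4;
    double phi = dihedral_and_grad(pt, pt2, pt3, pt4, &g1, &g2, &g3, &g4);
    double dydx;
    NumericMatrix::ConstRow row = m.dih_tab(tab, _);
    std::vector<double> yy(row.begin(), row.end());
    double val = interp_table(yy.data(), (int)yy.size(), -M_PI, M_PI, true, phi, &dydx);
    E[FLEX] += val;
    fx[i] -= dydx * g1.x; fy[i] -= dydx * g1.y; fz[i] -= dydx * g1.z;
    fx[j] -= dydx * g2.x; fy[j] -= dydx * g2.y; fz[j] -= dydx * g2.z;
    fx[k] -= dydx * g3.x; fy[k] -= dydx * g3.y; fz[k] -= dydx * g3.z;
    fx[l] -= dydx * g4.x; fy[l] -= dydx * g4.y; fz[l] -= dydx * g4.z;
  }

  // 12-10 Go contacts: U = eps (5 (r0/r)^12 - 6 (r0/r)^10)
  for (int c = 0; c < m.contacts.nrow(); ++c) {
    int i = (int)m.contacts(c, 0) - 1, j = (int)m.contacts(c, 1) - 1;
    double r0 = m.contacts(c, 2), eps = m.contacts(c, 3);
    double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2);
    double s2 = (r0 * r0) / r2;
    double s10 = s2 * s2 * s2 * s2 * s2, s12 = s10 * s2;
    E[GO] += eps * (5.0 * s12 - 6.0 * s10);
    // dU/dr = (60 eps / r) (s10 - s12); force magnitude along dx/r
    double fm = -60.0 * eps * (s10 - s12) / r2; // = -dU/dr * (1/r)
    fx[i] += fm * dx; fy[i] += fm * dy; fz[i] += fm * dz;
    fx[j] -= fm * dx; fy[j] -= fm * dy; fz[j] -= fm * dz;
  }

  // Morse terms (base pair, stacking, hydrogen bonds)
  const NumericMatrix* mats[3] = { &m.morse_bp, &m.morse_st, &m.morse_hb };
  const int slots[3] = { BP, STACK, HB };
  for (int t = 0; t < 3; ++t) {
    const NumericMatrix& M = *mats[t];
    for (int c = 0; c < M.nrow(); ++c) {
      int i = (int)M(c, 0) - 1, j = (int)M(c, 1) - 1;
      double r0 = M(c, 2), D = M(c, 3), al = M(c, 4);
      double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double ex = std::exp(-al * (r - r0));
      double om = 1.0 - ex;
      E[slots[t]] += D * (om * om - 1.0);
      double dU = 2.0 * D * al * ex * om;
      double fm = -dU / r;
      fx[i] += fm * dx; fy[i] += fm * dy; fz[i] += fm * dz;
      fx[j] -= fm * dx; fy[j] -= fm * dy; fz[j] -= fm * dz;
    }
  }

  // nonbonded pairs
  double cut_e2 = m.cut_elec * m.cut_elec, cut_o2 = m.cut_other * m.cut_other;
  double pref = m.kcoul / m.eps_r;
  for (size_t p = 0; p < pairs.size(); ++p) {
    int i = pairs[p].i, j = pairs[p].j;
    double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= cut_e2) continue;
    double r = std::sqrt(r2);
    if (r2 < cut_o2 && pairs[p].flag == 0) {
      // excluded volume
      double s2 = (m.ev_sigma * m.ev_sigma) / r2;
      double s12 = s2 * s2 * s2; s12 *= s12;
      E[EV] += m.ev_eps * s12;
      double fm = 12.0 * m.ev_eps * s12 / r2;
      fx[i] += fm * dx; fy[i] += fm * dy; fz[i] += fm * dz;
      fx[j] -= fm * dx; fy[j] -= fm * dy; fz[j] -= fm * dz;
      // HPS: protein-protein pairs where at least one bead is disordered
      if (!m.is_dna[i] && !m.is_dna[j] &&
          (m.disordered[i] || m.disordered[j])) {
        double lam = 0.5 * (m.hl[i] + m.hl[j]);
        double sig = 0.5 * (m.hs[i] + m.hs[j]);
        double sr2 = (sig * sig) / r2;
        double sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
        double ulj = 4.0 * m.hps_eps * (sr12 - sr6);
        double dulj = 4.0 * m.hps_eps * (-12.0 * sr12 + 6.0 * sr6) / r;
        double rc = std::pow(2.0, 1.0 / 6.0) * sig;
        double u, du;
        if (r <= rc) { u = ulj + (1.0 - lam) * m.hps_eps; du = dulj; }
        else { u = lam * ulj; du = lam * dulj; }
        E[HPS] += u;
        double fm = -du / r;
        fx[i] += fm * dx; fy[i] += fm * dy; fz[i] += fm * dz;
        fx[j] -= fm * dx; fy[j] -= fm * dy; fz[j] -= fm * dz;
      }
    }
    // electrostatics with pair-context phosphate charges
    double qi = m.is_phos[i] ? (m.is_dna[j] ? m.q_pd : m.q_pp) : m.charge[i];
    double qj = m.is_phos[j] ? (m.is_dna[i] ? m.q_pd : m.q_pp) : m.charge[j];
    double qq = qi * qj;
    if (qq != 0.0) {
      double ex = std::exp(-r / m.lambda_D);
      double u = pref * qq * ex / r;
      E[ELEC] += u;
      // dU/dr = -u (1/r + 1/lambda_D)
      double fm = u * (1.0 / r + 1.0 / m.lambda_D) / r;
      fx[i] += fm * dx; fy[i] += fm * dy; fz[i] += fm * dz;
      fx[j] -= fm * dx; fy[j] -= fm * dy; fz[j] -= fm * dz;
    }
  }
}

static const char* term_names[11] = {
  "bond", "angle", "dihedral", "go_contact", "flexible_local", "hps",
  "excluded_volume", "base_pair", "stacking", "hbond", "electrostatic"
};

// [[Rcpp::export]]
List cg_energy_forces_cpp(NumericMatrix pos, List ff) {
  Model m = build_model(ff);
  int n = pos.nrow();
  if (n != m.n) stop("position/topology size mismatch");
  std::vector<double> px(n), py(n), pz(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2); }
  std::vector<Pair> pairs;
  build_pairs(px, py, pz, m, m.cut_elec * m.cut_elec,
              m.cut_other * m.cut_other, pairs);
  double E[11];
  eval_all(px, py, pz, m, pairs, fx, fy, fz, E);
  NumericVector ev(12);
  CharacterVector nm(12);
  double tot = 0.0;
  for (int t = 0; t < 11; ++t) { ev[t] = E[t]; nm[t] = term_names[t]; tot += E[t]; }
  ev[11] = tot; nm[11] = "total";
  ev.attr("names") = nm;
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return List::create(_["energy"] = ev, _["forces"] = F);
}

// [[Rcpp::export]]
NumericMatrix cg_sample_velocities_cpp(double seed, NumericVector mass,
                                       double kT) {
  int n = mass.size();
  NumericMatrix v(n, 3);
  uint64_t s = (uint64_t)seed;
  for (int i = 0; i < n; ++i) {
    double sd = std::sqrt(kT / mass[i]);
    for (int d = 0; d < 3; ++d)
      v(i, d) = sd * gauss_at(s, 0xFFFFFFFFFFFFULL, 3 * (uint64_t)i + d);
  }
  return v;
}

// BAOAB Langevin integrator. gamma in 1/time-unit; gamma = 0 gives the
// velocity-Verlet (NVE) limit. Noise is indexed by absolute step so that
// restarting from (positions, velocities, step) continues the same stream.
// [[Rcpp::export]]
List cg_run_langevin_cpp(NumericMatrix pos0, NumericMatrix vel0, List ff,
                         double dt, double gamma, double temperature,
                         int n_steps, double seed, int save_every,
                         double start_step, int nlist_every, double skin) {
  Model m = build_model(ff);
  int n = pos0.nrow();
  if (n != m.n) stop("position/topology size mismatch");
  const double kB = 0.0019872041;
  double kT = kB * temperature;
  std::vector<double> px(n), py(n), pz(n), fx(n), fy(n), fz(n);
  std::vector<double> vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1); pz[i] = pos0(i, 2);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1); vz[i] = vel0(i, 2);
  }
  double c1 = std::exp(-gamma * dt);
  double c2 = (gamma > 0.0) ? std::sqrt(1.0 - c1 * c1) : 0.0;
  uint64_t us = (uint64_t)seed;

  double re = m.cut_elec + skin, ro = m.cut_other + skin;
  std::vector<Pair> pairs;
  build_pairs(px, py, pz, m, re * re, ro * ro, pairs);
  double E[11];
  eval_all(px, py, pz, m, pairs, fx, fy, fz, E);

  int n_saved = n_steps / save_every;
  NumericVector frames(Dimension(n, 3, n_saved));
  NumericVector saved_steps(n_saved), ke_saved(n_saved), pe_saved(n_saved);
  int isave = 0;

  for (int s = 0; s < n_steps; ++s) {
    uint64_t abs_step = (uint64_t)(start_step) + (uint64_t)s;
    // B
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / m.mass[i];
      vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
    }
    // A
    for (int i = 0; i < n; ++i) {
      px[i] += 0.5 * dt * vx[i]; py[i] += 0.5 * dt * vy[i]; pz[i] += 0.5 * dt * vz[i];
    }
    // O
    if (gamma > 0.0) {
      for (int i = 0; i < n; ++i) {
        double sd = std::sqrt(kT / m.mass[i]);
        vx[i] = c1 * vx[i] + c2 * sd * gauss_at(us, abs_step, 3 * (uint64_t)i + 0);
        vy[i] = c1 * vy[i] + c2 * sd * gauss_at(us, abs_step, 3 * (uint64_t)i + 1);
        vz[i] = c1 * vz[i] + c2 * sd * gauss_at(us, abs_step, 3 * (uint64_t)i + 2);
      }
    }
    // A
    for (int i = 0; i < n; ++i) {
      px[i] += 0.5 * dt * vx[i]; py[i] += 0.5 * dt * vy[i]; pz[i] += 0.5 * dt * vz[i];
    }
    // neighbor list refresh + sanity
    if ((s + 1) % nlist_every == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(px[i]) || !std::isfinite(py[i]) || !std::isfinite(pz[i]))
          stop("non-finite coordinates at step %d", (int)(start_step + s + 1));
      build_pairs(px, py, pz, m, re * re, ro * ro, pairs);
    }
    eval_all(px, py, pz, m, pairs, fx, fy, fz, E);
    // B
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / m.mass[i];
      vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
    }
    if ((s + 1) % save_every == 0) {
      double ke = 0.0, pe = 0.0;
      for (int t = 0; t < 11; ++t) pe += E[t];
      for (int i = 0; i < n; ++i) {
        frames[isave * 3 * n + 0 * n + i] = px[i];
        frames[isave * 3 * n + 1 * n + i] = py[i];
        frames[isave * 3 * n + 2 * n + i] = pz[i];
        ke += 0.5 * m.mass[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      }
      saved_steps[isave] = start_step + s + 1;
      ke_saved[isave] = ke;
      pe_saved[isave] = pe;
      ++isave;
    }
  }
  NumericMatrix posF(n, 3), velF(n, 3);
  for (int i = 0; i < n; ++i) {
    posF(i, 0) = px[i]; posF(i, 1) = py[i]; posF(i, 2) = pz[i];
    velF(i, 0) = vx[i]; velF(i, 1) = vy[i]; velF(i, 2) = vz[i];
  }
  return List::create(_["frames"] = frames, _["steps"] = saved_steps,
                      _["kinetic"] = ke_saved, _["potential"] = pe_saved,
                      _["final_pos"] = posF, _["final_vel"] = velF,
                      _["final_step"] = start_step + n_steps);
}
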