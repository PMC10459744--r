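// Compiled core of the capsomer simulator: pair potentials, elastic-network
// energies and forces, capsomer-cell Verlet neighbor listing, the velocity
// Verlet / Nose-Hoover chain integrator, and single-linkage cluster labels.
//
// Reduced units throughout: length = 1 small-bead diameter, energy = kBT at
// the target temperature, mass = 1 bead mass.  Positions are kept wrapped in
// [0, L)^3 and all distances use the minimum-image convention; L <= 0 means
// an open (non-periodic) box.

#include <Rcpp.h>
#include <cmath>
#include <functional>
#include <vector>

using namespace Rcpp;

static inline double mi(double d, double L) {
  if (L > 0.0) d -= L * std::round(d / L);
  return d;
}

static inline double wrap0L(double x, double L) {
  if (L <= 0.0) return x;
  x -= L * std::floor(x / L);
  if (x >= L) x -= L; // guard against floating-point roundup
  return x;
}

// ---------------------------------------------------------------------------
// Pair potential kernels

// Truncated & shifted LJ.  kind: 0 = WCA repulsive (eps = 1, rc = 2^(1/6) s),
// 1 = attractive (eps = eps_att, rc = 2.5 s).  Shift makes U(rc) = 0 exactly.
static inline void lj_params(bool attractive, double sig, double eps_att,
                             double &eps, double &rc2, double &shift) {
  if (attractive) {
    eps = eps_att;
    double rc = 2.5 * sig;
    rc2 = rc * rc;
    double s6 = std::pow(1.0 / 2.5, 6); // (sig/rc)^6
    shift = -4.0 * eps * (s6 * s6 - s6);
  } else {
    eps = 1.0;
    double rc = std::pow(2.0, 1.0 / 6.0) * sig;
    rc2 = rc * rc;
    shift = eps; // raw LJ at 2^(1/6) sigma is -eps
  }
}

// energy and f/r for shifted LJ at squared distance r2 (< rc2 assumed)
static inline void lj_eval(double r2, double sig, double eps, double shift,
                           double &e, double &fr) {
  double sr2 = sig * sig / r2;
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  e = 4.0 * eps * (sr12 - sr6) + shift;
  fr = 24.0 * eps * (2.0 * sr12 - sr6) / r2;
}

static inline void yukawa_eval(double r, double qq, double lB, double lamD,
                               double &e, double &fr) {
  e = lB * qq * std::exp(-r / lamD) / r;
  fr = e * (1.0 / lamD + 1.0 / r) / r; // f/r with F = fr * dx
}

// ---------------------------------------------------------------------------
// Model: bundles geometry/topology arrays plus a neighbor list

struct Model {
  int nb;                  // number of beads
  double L;                // box edge (<= 0: open)
  std::vector<double> x, y, z;
  std::vector<int> caps;   // capsomer id per bead (0-based)
  std::vector<int> role;   // 0 repulsive, 1 attractive, 2 interior
  std::vector<double> radius, charge, massv;
  // stretch edges
  std::vector<int> bi, bj;
  std::vector<double> rest;
  double ks;
  // bend edges: two oriented triangles per edge
  std::vector<int> t1a, t1b, t1c, t2a, t2b, t2c;
  double kb;
  double eps_att;
  bool use_elec;
  double lB, lamD, rc_elec;

  int ncaps;
  double rc_max;           // largest interaction cutoff
  double skin;

  // neighbor list (inter-capsomer bead pairs)
  std::vector<int> pi, pj;
  std::vector<double> psig;
  std::vector<char> patt, pelec;
  // intra-capsomer charged pairs (fixed topology)
  std::vector<int> qi_, qj_;

  std::vector<double> disp; // accumulated displacement since last build
  bool list_built;

  void init_from(NumericMatrix pos, double Lbox, IntegerVector caps_,
                 IntegerVector role_, NumericVector radius_,
                 NumericVector charge_, NumericVector mass_,
                 IntegerMatrix bonds, NumericVector rest_, double ks_,
                 IntegerMatrix bends, double kb_, double eps_att_,
                 bool use_elec_, double lB_, double lamD_, double rc_elec_,
                 double skin_) {
    nb = pos.nrow();
    L = Lbox;
    x.resize(nb); y.resize(nb); z.resize(nb);
    for (int i = 0; i < nb; ++i) {
      x[i] = wrap0L(pos(i, 0), L);
      y[i] = wrap0L(pos(i, 1), L);
      z[i] = wrap0L(pos(i, 2), L);
    }
    caps.assign(caps_.begin(), caps_.end());
    role.assign(role_.begin(), role_.end());
    radius.assign(radius_.begin(), radius_.end());
    charge.assign(charge_.begin(), charge_.end());
    massv.assign(mass_.begin(), mass_.end());
    int ns = bonds.nrow();
    bi.resize(ns); bj.resize(ns);
    for (int e = 0; e < ns; ++e) { bi[e] = bonds(e, 0); bj[e] = bonds(e, 1); }
    rest.assign(rest_.begin(), rest_.end());
    ks = ks_;
    int nbend = bends.nrow();
    t1a.resize(nbend); t1b.resize(nbend); t1c.resize(nbend);
    t2a.resize(nbend); t2b.resize(nbend); t2c.resize(nbend);
    // bend rows are (i, j, a1, b1, c1, a2, b2, c2): the shared edge followed
    // by the two oriented adjoining faces
    for (int e = 0; e < nbend; ++e) {
      t1a[e] = bends(e, 2); t1b[e] = bends(e, 3); t1c[e] = bends(e, 4);
      t2a[e] = bends(e, 5); t2b[e] = bends(e, 6); t2c[e] = bends(e, 7);
    }
    kb = kb_;
    eps_att = eps_att_;
    use_elec = use_elec_; lB = lB_; lamD = lamD_; rc_elec = rc_elec_;
    skin = skin_;

    ncaps = 0;
    for (int i = 0; i < nb; ++i) ncaps = std::max(ncaps, caps[i] + 1);

    double rmax = 0.0;
    for (int i = 0; i < nb; ++i) rmax = std::max(rmax, radius[i]);
    rc_max = 2.5 * 2.0 * 0.5;                        // attractive small-small
    rc_max = std::max(rc_max, std::pow(2.0, 1.0 / 6.0) * 2.0 * rmax);
    if (use_elec) rc_max = std::max(rc_max, rc_elec);

    // fixed intra-capsomer charged pair list
    qi_.clear(); qj_.clear();
    if (use_elec) {
      for (int i = 0; i < nb; ++i) {
        if (charge[i] == 0.0) continue;
        for (int j = i + 1; j < nb; ++j)
          if (charge[j] != 0.0 && caps[j] == caps[i]) {
            qi_.push_back(i); qj_.push_back(j);
          }
      }
    }
    disp.assign(nb, 0.0);
    list_built = false;
  }

  void pair_cutoff(int i, int j, double &sig, bool &att, bool &el,
                   double &rc) const {
    sig = radius[i] + radius[j];
    att = (role[i] == 1 && role[j] == 1);
    el = use_elec && charge[i] != 0.0 && charge[j] != 0.0;
    double rc_st = att ? 2.5 * sig : std::pow(2.0, 1.0 / 6.0) * sig;
    rc = el ? std::max(rc_st, rc_elec) : rc_st;
  }

  void build_nlist() {
    pi.clear(); pj.clear(); psig.clear(); patt.clear(); pelec.clear();
    // capsomer centroids (unwrapped relative to first bead) and extents
    std::vector<double> cx(ncaps), cy(ncaps), cz(ncaps), ext(ncaps, 0.0);
    std::vector<int> first(ncaps, -1), cnt(ncaps, 0);
    for (int i = 0; i < nb; ++i) if (first[caps[i]] < 0) first[caps[i]] = i;
    std::vector<double> sx(ncaps, 0.0), sy(ncaps, 0.0), sz(ncaps, 0.0);
    for (int i = 0; i < nb; ++i) {
      int c = caps[i], f = first[c];
      sx[c] += x[f] + mi(x[i] - x[f], L);
      sy[c] += y[f] + mi(y[i] - y[f], L);
      sz[c] += z[f] + mi(z[i] - z[f], L);
      cnt[c]++;
    }
    for (int c = 0; c < ncaps; ++c) {
      cx[c] = sx[c] / cnt[c]; cy[c] = sy[c] / cnt[c]; cz[c] = sz[c] / cnt[c];
    }
    for (int i = 0; i < nb; ++i) {
      int c = caps[i];
      double dx = mi(x[i] - cx[c], L), dy = mi(y[i] - cy[c], L),
             dz = mi(z[i] - cz[c], L);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) + radius[i];
      ext[c] = std::max(ext[c], d);
    }
    // bead ids per capsomer
    std::vector<std::vector<int> > members(ncaps);
    for (int i = 0; i < nb; ++i) members[caps[i]].push_back(i);

    for (int a = 0; a < ncaps; ++a) {
      for (int b = a + 1; b < ncaps; ++b) {
        double dx = mi(cx[a] - cx[b], L), dy = mi(cy[a] - cy[b], L),
               dz = mi(cz[a] - cz[b], L);
        double dcc = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (dcc > ext[a] + ext[b] + rc_max + skin) continue;
        for (size_t u = 0; u < members[a].size(); ++u) {
          int i = members[a][u];
          for (size_t v = 0; v < members[b].size(); ++v) {
            int j = members[b][v];
            double sig, rc; bool att, el;
            pair_cutoff(i, j, sig, att, el, rc);
            double ddx = mi(x[i] - x[j], L), ddy = mi(y[i] - y[j], L),
                   ddz = mi(z[i] - z[j], L);
            double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
            double rl = rc + skin;
            if (r2 < rl * rl) {
              pi.push_back(i); pj.push_back(j);
              psig.push_back(sig);
              patt.push_back(att ? 1 : 0);
              pelec.push_back(el ? 1 : 0);
            }
          }
        }
      }
    }
    std::fill(disp.begin(), disp.end(), 0.0);
    list_built = true;
  }

  void maybe_rebuild() {
    if (!list_built) { build_nlist(); return; }
    double half = 0.5 * skin;
    for (int i = 0; i < nb; ++i)
      if (disp[i] > half) { build_nlist(); return; }
  }

  // energy components and (optionally) forces
  void compute(bool want_forces, std::vector<double> &fx,
               std::vector<double> &fy, std::vector<double> &fz,
               double &e_rep, double &e_att, double &e_bend,
               double &e_stretch, double &e_elec) {
    e_rep = e_att = e_bend = e_stretch = e_elec = 0.0;
    if (want_forces) {
      fx.assign(nb, 0.0); fy.assign(nb, 0.0); fz.assign(nb, 0.0);
    }
    // inter-capsomer pairs from neighbor list
    for (size_t p = 0; p < pi.size(); ++p) {
      int i = pi[p], j = pj[p];
      double dx = mi(x[i] - x[j], L), dy = mi(y[i] - y[j], L),
             dz = mi(z[i] - z[j], L);
      double r2 = dx * dx + dy * dy + dz * dz;
      double sig = psig[p];
      bool att = patt[p] != 0;
      double eps, rc2, shift;
      lj_params(att, sig, eps_att, eps, rc2, shift);
      if (r2 < rc2) {
        double e, fr;
        lj_eval(r2, sig, eps, shift, e, fr);
        if (att) e_att += e; else e_rep += e;
        if (want_forces) {
          fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
          fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
        }
      }
      if (pelec[p] != 0) {
        double r = std::sqrt(r2);
        if (r < rc_elec) {
          double e, fr;
          yukawa_eval(r, charge[i] * charge[j], lB, lamD, e, fr);
          e_elec += e;
          if (want_forces) {
            fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
            fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
          }
        }
      }
    }
    // intra-capsomer electrostatics (fixed pair list)
    for (size_t p = 0; p < qi_.size(); ++p) {
      int i = qi_[p], j = qj_[p];
      double dx = mi(x[i] - x[j], L), dy = mi(y[i] - y[j], L),
             dz = mi(z[i] - z[j], L);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < rc_elec) {
        double e, fr;
        yukawa_eval(r, charge[i] * charge[j], lB, lamD, e, fr);
        e_elec += e;
        if (want_forces) {
          fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
          fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
        }
      }
    }
    // stretching
    for (size_t e = 0; e < bi.size(); ++e) {
      int i = bi[e], j = bj[e];
      double dx = mi(x[i] - x[j], L), dy = mi(y[i] - y[j], L),
             dz = mi(z[i] - z[j], L);
      double l = std::sqrt(dx * dx + dy * dy + dz * dz);
      double d = l - rest[e];
      e_stretch += 0.5 * ks * d * d;
      if (want_forces && l > 0.0) {
        double fr = -ks * d / l;
        fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
        fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
      }
    }
    // bending: E = kb (1 - n1.n2) per edge
    for (size_t e = 0; e < t1a.size(); ++e) {
      int a = t1a[e], b = t1b[e], c = t1c[e];
      int d = t2a[e], f = t2b[e], g = t2c[e];
      // unwrap triangle vertices relative to a and d
      double ax = x[a], ay = y[a], az = z[a];
      double bx_ = ax + mi(x[b] - ax, L), by_ = ay + mi(y[b] - ay, L),
             bz_ = az + mi(z[b] - az, L);
      double cx_ = ax + mi(x[c] - ax, L), cy_ = ay + mi(y[c] - ay, L),
             cz_ = az + mi(z[c] - az, L);
      double dx_ = x[d], dy_ = y[d], dz_ = z[d];
      double fx_ = dx_ + mi(x[f] - dx_, L), fy_ = dy_ + mi(y[f] - dy_, L),
             fz_ = dz_ + mi(z[f] - dz_, L);
      double gx_ = dx_ + mi(x[g] - dx_, L), gy_ = dy_ + mi(y[g] - dy_, L),
             gz_ = dz_ + mi(z[g] - dz_, L);
      // n1 = (b-a) x (c-a)
      double u1 = bx_ - ax, u2 = by_ - ay, u3 = bz_ - az;
      double v1 = cx_ - ax, v2 = cy_ - ay, v3 = cz_ - az;
      double n1x = u2 * v3 - u3 * v2, n1y = u3 * v1 - u1 * v3,
             n1z = u1 * v2 - u2 * v1;
      double w1 = fx_ - dx_, w2 = fy_ - dy_, w3 = fz_ - dz_;
      double s1 = gx_ - dx_, s2 = gy_ - dy_, s3 = gz_ - dz_;
      double n2x = w2 * s3 - w3 * s2, n2y = w3 * s1 - w1 * s3,
             n2z = w1 * s2 - w2 * s1;
      double m1 = std::sqrt(n1x * n1x + n1y * n1y + n1z * n1z);
      double m2 = std::sqrt(n2x * n2x + n2y * n2y + n2z * n2z);
      if (m1 <= 0.0 || m2 <= 0.0) continue; // degenerate face
      double ux = n1x / m1, uy = n1y / m1, uz = n1z / m1;
      double vx = n2x / m2, vy = n2y / m2, vz = n2z / m2;
      double cosang = ux * vx + uy * vy + uz * vz;
      e_bend += kb * (1.0 - cosang);
      if (want_forces) {
        // dc/dn1 = (v - c u)/m1 ; dc/dn2 = (u - c v)/m2
        double p1x = (vx - cosang * ux) / m1, p1y = (vy - cosang * uy) / m1,
               p1z = (vz - cosang * uz) / m1;
        double p2x = (ux - cosang * vx) / m2, p2y = (uy - cosang * vy) / m2,
               p2z = (uz - cosang * vz) / m2;
        // grad of (n . w) wrt vertices: a -> (b-c) x w, b -> (c-a) x w,
        // c -> (a-b) x w (using in-triangle coordinates)
        // F = +kb * grad(cosang)
        double e1x, e1y, e1z;
        // triangle 1, vertex a: (b - c) x p1
        e1x = (by_ - cy_) * p1z - (bz_ - cz_) * p1y;
        e1y = (bz_ - cz_) * p1x - (bx_ - cx_) * p1z;
        e1z = (bx_ - cx_) * p1y - (by_ - cy_) * p1x;
        fx[a] += kb * e1x; fy[a] += kb * e1y; fz[a] += kb * e1z;
        // vertex b: (c - a) x p1
        e1x = (cy_ - ay) * p1z - (cz_ - az) * p1y;
        e1y = (cz_ - az) * p1x - (cx_ - ax) * p1z;
        e1z = (cx_ - ax) * p1y - (cy_ - ay) * p1x;
        fx[b] += kb * e1x; fy[b] += kb * e1y; fz[b] += kb * e1z;
        // vertex c: (a - b) x p1
        e1x = (ay - by_) * p1z - (az - bz_) * p1y;
        e1y = (az - bz_) * p1x - (ax - bx_) * p1z;
        e1z = (ax - bx_) * p1y - (ay - by_) * p1x;
        fx[c] += kb * e1x; fy[c] += kb * e1y; fz[c] += kb * e1z;
        // triangle 2, vertex d: (f - g) x p2
        e1x = (fy_ - gy_) * p2z - (fz_ - gz_) * p2y;
        e1y = (fz_ - gz_) * p2x - (fx_ - gx_) * p2z;
        e1z = (fx_ - gx_) * p2y - (fy_ - gy_) * p2x;
        fx[d] += kb * e1x; fy[d] += kb * e1y; fz[d] += kb * e1z;
        // vertex f: (g - d) x p2
        e1x = (gy_ - dy_) * p2z - (gz_ - dz_) * p2y;
        e1y = (gz_ - dz_) * p2x - (gx_ - dx_) * p2z;
        e1z = (gx_ - dx_) * p2y - (gy_ - dy_) * p2x;
        fx[f] += kb * e1x; fy[f] += kb * e1y; fz[f] += kb * e1z;
        // vertex g: (d - f) x p2
        e1x = (dy_ - fy_) * p2z - (dz_ - fz_) * p2y;
        e1y = (dz_ - fz_) * p2x - (dx_ - fx_) * p2z;
        e1z = (dx_ - fx_) * p2y - (dy_ - fy_) * p2x;
        fx[g] += kb * e1x; fy[g] += kb * e1y; fz[g] += kb * e1z;
      }
    }
  }
};

static Model make_model(NumericMatrix pos, double L, IntegerVector caps,
                        IntegerVector role, NumericVector radius,
                        NumericVector charge, NumericVector mass,
                        IntegerMatrix bonds, NumericVector rest, double ks,
                        IntegerMatrix bends, double kb, double eps_att,
                        bool use_elec, double lB, double lamD, double rc_elec,
                        double skin) {
  Model m;
  m.init_from(pos, L, caps, role, radius, charge, mass, bonds, rest, ks,
              bends, kb, eps_att, use_elec, lB, lamD, rc_elec, skin);
  return m;
}

// [[Rcpp::export]]
List cpp_evaluate(NumericMatrix pos, double L, IntegerVector caps,
                  IntegerVector role, NumericVector radius,
                  NumericVector charge, NumericVector mass,
                  IntegerMatrix bonds, NumericVector rest, double ks,
                  IntegerMatrix bends, double kb, double eps_att,
                  bool use_elec, double lB, double lamD, double rc_elec,
                  double skin, bool want_forces) {
  Model m = make_model(pos, L, caps, role, radius, charge, mass, bonds, rest,
                       ks, bends, kb, eps_att, use_elec, lB, lamD, rc_elec,
                       skin);
  m.build_nlist();
  std::vector<double> fx, fy, fz;
  double er, ea, eb, es, ee;
  m.compute(want_forces, fx, fy, fz, er, ea, eb, es, ee);
  List out = List::create(
      _["steric_repulsive"] = er, _["steric_attractive"] = ea,
      _["bending"] = eb, _["stretching"] = es, _["electrostatic"] = ee);
  if (want_forces) {
    NumericMatrix F(m.nb, 3);
    for (int i = 0; i < m.nb; ++i) {
      F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i];
    }
    out["forces"] = F;
  }
  return out;
}

// Inter-capsomer bead pairs currently held in the neighbor list
// (for completeness checks against an all-pairs search).
// [[Rcpp::export]]
List cpp_neighbor_pairs(NumericMatrix pos, double L, IntegerVector caps,
                        IntegerVector role, NumericVector radius,
                        NumericVector charge, NumericVector mass,
                        IntegerMatrix bonds, NumericVector rest, double ks,
                        IntegerMatrix bends, double kb, double eps_att,
                        bool use_elec, double lB, double lamD, double rc_elec,
                        double skin) {
  Model m = make_model(pos, L, caps, role, radius, charge, mass, bonds, rest,
                       ks, bends, kb, eps_att, use_elec, lB, lamD, rc_elec,
                       skin);
  m.build_nlist();
  int np = (int)m.pi.size();
  IntegerVector I(np), J(np);
  for (int p = 0; p < np; ++p) { I[p] = m.pi[p] + 1; J[p] = m.pj[p] + 1; }
  return List::create(_["i"] = I, _["j"] = J);
}

// ---------------------------------------------------------------------------
// Integrator

// mode: 0 = NVE, 1 = NVT (Nose-Hoover chain), 2 = damped quench
// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, double L,
                IntegerVector caps, IntegerVector role, NumericVector radius,
                NumericVector charge, NumericVector mass, IntegerMatrix bonds,
                NumericVector rest, double ks, IntegerMatrix bends, double kb,
                double eps_att, bool use_elec, double lB, double lamD,
                double rc_elec, double skin, double dt, int nsteps, int mode,
                double Ttarget, double tau, int nchain,
                NumericVector xi0, NumericVector vxi0,
                int sample_every, bool save_frames) {
  Model m = make_model(pos, L, caps, role, radius, charge, mass, bonds, rest,
                       ks, bends, kb, eps_att, use_elec, lB, lamD, rc_elec,
                       skin);
  int nb = m.nb;
  std::vector<double> vx(nb), vy(nb), vz(nb);
  for (int i = 0; i < nb; ++i) {
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  double ndf = 3.0 * nb - 3.0;

  // Nose-Hoover chain state
  int M = std::max(nchain, 2);
  std::vector<double> xi(M, 0.0), vxi(M, 0.0), Q(M);
  for (int k = 0; k < M && k < xi0.size(); ++k) xi[k] = xi0[k];
  for (int k = 0; k < M && k < vxi0.size(); ++k) vxi[k] = vxi0[k];
  Q[0] = ndf * Ttarget * tau * tau;
  for (int k = 1; k < M; ++k) Q[k] = Ttarget * tau * tau;
  // Suzuki-Yoshida 3-stage weights
  double w1 = 1.0 / (2.0 - std::pow(2.0, 1.0 / 3.0));
  double sy[3] = {w1, 1.0 - 2.0 * w1, w1};

  std::vector<double> fx, fy, fz;
  double er, ea, eb, es, ee;
  m.build_nlist();
  m.compute(true, fx, fy, fz, er, ea, eb, es, ee);

  int nsamp = (sample_every > 0) ? (nsteps / sample_every + 1) : 1;
  NumericVector s_step(nsamp), s_time(nsamp), s_ke(nsamp), s_rep(nsamp),
      s_att(nsamp), s_bend(nsamp), s_stretch(nsamp), s_elec(nsamp),
      s_temp(nsamp), s_cons(nsamp);
  List frames(save_frames ? nsamp : 0);
  int isamp = 0;

  double ke = 0.0;
  for (int i = 0; i < nb; ++i)
    ke += 0.5 * m.massv[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);

  // Nose-Hoover chain half update; scales velocities, advances chain
  // variables; ke2 = 2 * kinetic energy, updated in place.
  double ke2 = 2.0 * ke;
  #define NHC_HALF(dt2)                                                     \
    {                                                                       \
      double scale = 1.0;                                                   \
      for (int isy = 0; isy < 3; ++isy) {                                   \
        double wdt = sy[isy] * (dt2), wdt2 = 0.5 * wdt, wdt4 = 0.25 * wdt;  \
        double G = (Q[M - 2] * vxi[M - 2] * vxi[M - 2] - Ttarget) / Q[M - 1];\
        vxi[M - 1] += G * wdt2;                                             \
        for (int k = M - 2; k >= 0; --k) {                                  \
          double efac = std::exp(-wdt4 * vxi[k + 1]);                       \
          G = (k == 0) ? (ke2 - ndf * Ttarget) / Q[0]                       \
                       : (Q[k - 1] * vxi[k - 1] * vxi[k - 1] - Ttarget) / Q[k];\
          vxi[k] = (vxi[k] * efac + G * wdt2) * efac;                       \
        }                                                                   \
        double s = std::exp(-wdt * vxi[0]);                                 \
        scale *= s;                                                         \
        ke2 *= s * s;                                                       \
        for (int k = 0; k < M; ++k) xi[k] += wdt * vxi[k];                  \
        for (int k = 0; k <= M - 2; ++k) {                                  \
          double efac = std::exp(-wdt4 * vxi[k + 1]);                       \
          G = (k == 0) ? (ke2 - ndf * Ttarget) / Q[0]                       \
                       : (Q[k - 1] * vxi[k - 1] * vxi[k - 1] - Ttarget) / Q[k];\
          vxi[k] = (vxi[k] * efac + G * wdt2) * efac;                       \
        }                                                                   \
        G = (Q[M - 2] * vxi[M - 2] * vxi[M - 2] - Ttarget) / Q[M - 1];      \
        vxi[M - 1] += G * wdt2;                                             \
      }                                                                     \
      for (int i = 0; i < nb; ++i) {                                        \
        vx[i] *= scale; vy[i] *= scale; vz[i] *= scale;                     \
      }                                                                     \
    }

  #define RECORD(step)                                                      \
    {                                                                       \
      ke = 0.0;                                                             \
      for (int i = 0; i < nb; ++i)                                          \
        ke += 0.5 * m.massv[i] *                                            \
              (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);              \
      double pe = er + ea + eb + es + ee;                                   \
      double cons = ke + pe;                                                \
      if (mode == 1) {                                                      \
        for (int k = 0; k < M; ++k) cons += 0.5 * Q[k] * vxi[k] * vxi[k];   \
        cons += ndf * Ttarget * xi[0];                                      \
        for (int k = 1; k < M; ++k) cons += Ttarget * xi[k];                \
      }                                                                     \
      s_step[isamp] = step; s_time[isamp] = (step) * dt;                    \
      s_ke[isamp] = ke; s_rep[isamp] = er; s_att[isamp] = ea;               \
      s_bend[isamp] = eb; s_stretch[isamp] = es; s_elec[isamp] = ee;        \
      s_temp[isamp] = 2.0 * ke / ndf; s_cons[isamp] = cons;                 \
      if (save_frames) {                                                    \
        NumericMatrix fr(nb, 3);                                            \
        for (int i = 0; i < nb; ++i) {                                      \
          fr(i, 0) = m.x[i]; fr(i, 1) = m.y[i]; fr(i, 2) = m.z[i];          \
        }                                                                   \
        frames[isamp] = fr;                                                 \
      }                                                                     \
      ++isamp;                                                              \
    }

  if (sample_every > 0) RECORD(0);

  for (int step = 1; step <= nsteps; ++step) {
    if (mode == 1) {
      ke2 = 0.0;
      for (int i = 0; i < nb; ++i)
        ke2 += m.massv[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      NHC_HALF(0.5 * dt);
    }
    if (mode == 2) {
      // damped quench: semi-implicit Euler + global velocity reset when the
      // power F.v turns negative (keeps the minimizer monotone)
      double P = 0.0;
      for (int i = 0; i < nb; ++i) {
        vx[i] += dt * fx[i] / m.massv[i];
        vy[i] += dt * fy[i] / m.massv[i];
        vz[i] += dt * fz[i] / m.massv[i];
        P += fx[i] * vx[i] + fy[i] * vy[i] + fz[i] * vz[i];
      }
      if (P < 0.0)
        for (int i = 0; i < nb; ++i) { vx[i] = 0; vy[i] = 0; vz[i] = 0; }
      for (int i = 0; i < nb; ++i) {
        double dx = dt * vx[i], dy = dt * vy[i], dz = dt * vz[i];
        m.x[i] = wrap0L(m.x[i] + dx, L);
        m.y[i] = wrap0L(m.y[i] + dy, L);
        m.z[i] = wrap0L(m.z[i] + dz, L);
        m.disp[i] += std::sqrt(dx * dx + dy * dy + dz * dz);
      }
    } else {
      // velocity Verlet
      for (int i = 0; i < nb; ++i) {
        double im = 1.0 / m.massv[i];
        vx[i] += 0.5 * dt * fx[i] * im;
        vy[i] += 0.5 * dt * fy[i] * im;
        vz[i] += 0.5 * dt * fz[i] * im;
        double dx = dt * vx[i], dy = dt * vy[i], dz = dt * vz[i];
        m.x[i] = wrap0L(m.x[i] + dx, L);
        m.y[i] = wrap0L(m.y[i] + dy, L);
        m.z[i] = wrap0L(m.z[i] + dz, L);
        m.disp[i] += std::sqrt(dx * dx + dy * dy + dz * dz);
      }
    }
    m.maybe_rebuild();
    m.compute(true, fx, fy, fz, er, ea, eb, es, ee);
    if (mode != 2) {
      for (int i = 0; i < nb; ++i) {
        double im = 1.0 / m.massv[i];
        vx[i] += 0.5 * dt * fx[i] * im;
        vy[i] += 0.5 * dt * fy[i] * im;
        vz[i] += 0.5 * dt * fz[i] * im;
      }
    }
    if (mode == 1) {
      ke2 = 0.0;
      for (int i = 0; i < nb; ++i)
        ke2 += m.massv[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      NHC_HALF(0.5 * dt);
    }
    for (int i = 0; i < nb; ++i) {
      if (!std::isfinite(m.x[i]) || !std::isfinite(vx[i]) ||
          !std::isfinite(m.y[i]) || !std::isfinite(vy[i]) ||
          !std::isfinite(m.z[i]) || !std::isfinite(vz[i]))
        stop("integration blew up at step %d (non-finite coordinate "
             "or velocity); reduce the timestep", step);
    }
    if (sample_every > 0 && step % sample_every == 0) RECORD(step);
  }

  NumericMatrix Pout(nb, 3), Vout(nb, 3);
  for (int i = 0; i < nb; ++i) {
    Pout(i, 0) = m.x[i]; Pout(i, 1) = m.y[i]; Pout(i, 2) = m.z[i];
    Vout(i, 0) = vx[i]; Vout(i, 1) = vy[i]; Vout(i, 2) = vz[i];
  }
  NumericVector xiout(M), vxiout(M);
  for (int k = 0; k < M; ++k) { xiout[k] = xi[k]; vxiout[k] = vxi[k]; }

  DataFrame samples = DataFrame::create(
      _["step"] = s_step, _["time"] = s_time, _["kinetic"] = s_ke,
      _["steric_repulsive"] = s_rep, _["steric_attractive"] = s_att,
      _["bending"] = s_bend, _["stretching"] = s_stretch,
      _["electrostatic"] = s_elec, _["temperature"] = s_temp,
      _["conserved"] = s_cons);
  return List::create(_["pos"] = Pout, _["vel"] = Vout, _["xi"] = xiout,
                      _["vxi"] = vxiout, _["samples"] = samples,
                      _["frames"] = frames);
}

// ---------------------------------------------------------------------------
// Cluster detection: single linkage over capsomers, two capsomers linked iff
// their minimum bead-bead center distance < dcut.

// [[Rcpp::export]]
IntegerVector cpp_cluster_labels(NumericMatrix pos, double L,
                                 IntegerVector caps, double dcut) {
  int nb = pos.nrow();
  int nc = 0;
  for (int i = 0; i < nb; ++i) nc = std::max(nc, caps[i] + 1);
  std::vector<std::vector<int> > members(nc);
  for (int i = 0; i < nb; ++i) members[caps[i]].push_back(i);

  // centroids (unwrapped) and extents for prefilter
  std::vector<double> cx(nc), cy(nc), cz(nc), ext(nc, 0.0);
  for (int c = 0; c < nc; ++c) {
    int f = members[c][0];
    double sx = 0, sy = 0, sz = 0;
    for (size_t u = 0; u < members[c].size(); ++u) {
      int i = members[c][u];
      sx += pos(f, 0) + mi(pos(i, 0) - pos(f, 0), L);
      sy += pos(f, 1) + mi(pos(i, 1) - pos(f, 1), L);
      sz += pos(f, 2) + mi(pos(i, 2) - pos(f, 2), L);
    }
    cx[c] = sx / members[c].size();
    cy[c] = sy / members[c].size();
    cz[c] = sz / members[c].size();
    for (size_t u = 0; u < members[c].size(); ++u) {
      int i = members[c][u];
      double dx = mi(pos(i, 0) - cx[c], L), dy = mi(pos(i, 1) - cy[c], L),
             dz = mi(pos(i, 2) - cz[c], L);
      ext[c] = std::max(ext[c], std::sqrt(dx * dx + dy * dy + dz * dz));
    }
  }

  std::vector<int> parent(nc);
  for (int c = 0; c < nc; ++c) parent[c] = c;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };

  for (int a = 0; a < nc; ++a) {
    for (int b = a + 1; b < nc; ++b) {
      double dx = mi(cx[a] - cx[b], L), dy = mi(cy[a] - cy[b], L),
             dz = mi(cz[a] - cz[b], L);
      if (std::sqrt(dx * dx + dy * dy + dz * dz) >
          ext[a] + ext[b] + dcut)
        continue;
      bool linked = false;
      for (size_t u = 0; u < members[a].size() && !linked; ++u) {
        int i = members[a][u];
        for (size_t v = 0; v < members[b].size(); ++v) {
          int j = members[b][v];
          double ddx = mi(pos(i, 0) - pos(j, 0), L),
                 ddy = mi(pos(i, 1) - pos(j, 1), L),
                 ddz = mi(pos(i, 2) - pos(j, 2), L);
          if (ddx * ddx + ddy * ddy + ddz * ddz < dcut * dcut) {
            linked = true; break;
          }
        }
      }
      if (linked) {
        int ra = find(a), rb = find(b);
        if (ra != rb) parent[ra] = rb;
      }
    }
  }
  IntegerVector lab(nc);
  std::vector<int> remap(nc, -1);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    int r = find(c);
    if (remap[r] < 0) remap[r] = ++next;
    lab[c] = remap[r];
  }
  return lab;
}

// Any bead-bead overlap (distance < sum of radii) between a candidate
// capsomer and the beads already placed?  Used by random placement.
// [[Rcpp::export]]
bool cpp_any_overlap(NumericMatrix existing, NumericVector exrad,
                     NumericMatrix cand, NumericVector candrad, double L) {
  int ne = existing.nrow(), nc = cand.nrow();
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < ne; ++i) {
      double dx = mi(existing(i, 0) - cand(j, 0), L);
      double dy = mi(existing(i, 1) - cand(j, 1), L);
      double dz = mi(existing(i, 2) - cand(j, 2), L);
      double s = exrad[i] + candrad[j];
      if (dx * dx + dy * dy + dz * dz < s * s) return true;
    }
  }
  return false;
}

// Minimum bead-bead distance between two capsomers (diagnostics / fixtures).
// [[Rcpp::export]]
double cpp_min_pair_dist(NumericMatrix a, NumericMatrix b, double L) {
  double best = R_PosInf;
  for (int i = 0; i < a.nrow(); ++i)
    for (int j = 0; j < b.nrow(); ++j) {
      double dx = mi(a(i, 0) - b(j, 0), L), dy = mi(a(i, 1) - b(j, 1), L),
             dz = mi(a(i, 2) - b(j, 2), L);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < best) best = d;
    }
  return best;
}
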