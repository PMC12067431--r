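#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// minimum-image displacement component
static inline double mi(double dx, double L) {
  return dx - L * std::nearbyint(dx / L);
}

// fast minimum image, valid when |dx| < 1.5 L (positions kept in [0, L))
static inline double mif(double dx, double L) {
  if (dx > 0.5 * L) dx -= L;
  else if (dx < -0.5 * L) dx += L;
  return dx;
}

// ---------------------------------------------------------------------------
// fixed-radius neighbour pairs under minimum image (cell list with O(N^2)
// fallback when the box holds fewer than 3 cells per edge)
// ---------------------------------------------------------------------------

struct PairAcc {
  std::vector<int> i, j;
  std::vector<double> d;
  void add(int a, int b, double dist) { i.push_back(a); j.push_back(b); d.push_back(dist); }
};

// [[Rcpp::export]]
DataFrame cpp_neighbor_pairs(NumericMatrix A, Nullable<NumericMatrix> B_,
                             double L, double cutoff) {
  const double rc2 = cutoff * cutoff;
  PairAcc acc;
  if (B_.isNotNull()) {
    NumericMatrix B(B_);
    const int na = A.nrow(), nb = B.nrow();
    for (int a = 0; a < na; ++a) {
      for (int b = 0; b < nb; ++b) {
        double dx = mi(A(a,0)-B(b,0), L), dy = mi(A(a,1)-B(b,1), L), dz = mi(A(a,2)-B(b,2), L);
        double r2 = dx*dx + dy*dy + dz*dz;
        if (r2 < rc2) acc.add(a + 1, b + 1, std::sqrt(r2));
      }
    }
  } else {
    const int n = A.nrow();
    int nc = (int)std::floor(L / cutoff);
    if (nc >= 3 && n > 64) {
      // cell list
      double cell = L / nc;
      std::vector<std::vector<int>> cells(nc * nc * nc);
      std::vector<int> cx(n), cy(n), cz(n);
      for (int a = 0; a < n; ++a) {
        int ix = (int)std::floor(A(a,0) / cell); ix = ((ix % nc) + nc) % nc;
        int iy = (int)std::floor(A(a,1) / cell); iy = ((iy % nc) + nc) % nc;
        int iz = (int)std::floor(A(a,2) / cell); iz = ((iz % nc) + nc) % nc;
        cx[a]=ix; cy[a]=iy; cz[a]=iz;
        cells[(ix*nc + iy)*nc + iz].push_back(a);
      }
      for (int a = 0; a < n; ++a) {
        for (int ox = -1; ox <= 1; ++ox) for (int oy = -1; oy <= 1; ++oy) for (int oz = -1; oz <= 1; ++oz) {
          int ix = (cx[a]+ox+nc)%nc, iy = (cy[a]+oy+nc)%nc, iz = (cz[a]+oz+nc)%nc;
          const std::vector<int>& cc = cells[(ix*nc + iy)*nc + iz];
          for (int b : cc) {
            if (b <= a) continue;
            double dx = mi(A(a,0)-A(b,0), L), dy = mi(A(a,1)-A(b,1), L), dz = mi(A(a,2)-A(b,2), L);
            double r2 = dx*dx + dy*dy + dz*dz;
            if (r2 < rc2) acc.add(a + 1, b + 1, std::sqrt(r2));
          }
        }
      }
    } else {
      for (int a = 0; a < n; ++a) for (int b = a + 1; b < n; ++b) {
        double dx = mi(A(a,0)-A(b,0), L), dy = mi(A(a,1)-A(b,1), L), dz = mi(A(a,2)-A(b,2), L);
        double r2 = dx*dx + dy*dy + dz*dz;
        if (r2 < rc2) acc.add(a + 1, b + 1, std::sqrt(r2));
      }
    }
  }
  return DataFrame::create(_["i"] = acc.i, _["j"] = acc.j, _["dist"] = acc.d);
}

// ---------------------------------------------------------------------------
// Ewald summation (real + reciprocal + self), energies in kBT with
// prefactor lambda_B* applied by the caller through `prefac`
// ---------------------------------------------------------------------------

struct EwaldPlan {
  std::vector<double> kx, ky, kz, Ak; // reciprocal vectors and weights
};

static EwaldPlan ewald_plan(double L, double alpha, int kmax) {
  EwaldPlan pl;
  const double twopiL = 2.0 * M_PI / L;
  const double kmax2 = (double)kmax * kmax;
  for (int nx = 0; nx <= kmax; ++nx) {
    int ny0 = (nx == 0) ? 0 : -kmax;
    for (int ny = ny0; ny <= kmax; ++ny) {
      int nz0 = (nx == 0 && ny == 0) ? 1 : -kmax;
      for (int nz = nz0; nz <= kmax; ++nz) {
        double n2 = (double)nx*nx + (double)ny*ny + (double)nz*nz;
        if (n2 > kmax2) continue;
        double kxv = twopiL*nx, kyv = twopiL*ny, kzv = twopiL*nz;
        double k2 = kxv*kxv + kyv*kyv + kzv*kzv;
        // half-space: factor 2 folded into Ak
        pl.kx.push_back(kxv); pl.ky.push_back(kyv); pl.kz.push_back(kzv);
        pl.Ak.push_back(2.0 * std::exp(-k2 / (4.0*alpha*alpha)) / k2);
      }
    }
  }
  return pl;
}

// returns energy; accumulates forces into F
static double ewald_compute(const std::vector<double>& x, const std::vector<double>& y,
                            const std::vector<double>& z, const std::vector<double>& q,
                            double L, double alpha, double rc, const EwaldPlan& pl,
                            double prefac, std::vector<double>& Fx,
                            std::vector<double>& Fy, std::vector<double>& Fz) {
  const int n = (int)q.size();
  const double V = L * L * L;
  double e_real = 0.0, e_recip = 0.0, e_self = 0.0;
  const double rc2 = rc * rc;
  const double twos = 2.0 * alpha / std::sqrt(M_PI);
  // real space, minimum image within cutoff
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      double dx = mi(x[a]-x[b], L), dy = mi(y[a]-y[b], L), dz = mi(z[a]-z[b], L);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      double qq = q[a]*q[b];
      double er = std::erfc(alpha * r);
      e_real += qq * er / r;
      double fr = prefac * qq * (er / r2 + twos * std::exp(-alpha*alpha*r2) / r) / r;
      Fx[a] += fr*dx; Fy[a] += fr*dy; Fz[a] += fr*dz;
      Fx[b] -= fr*dx; Fy[b] -= fr*dy; Fz[b] -= fr*dz;
    }
  }
  // reciprocal space via structure factors
  const int nk = (int)pl.kx.size();
  std::vector<double> cs(n), sn(n);
  for (int k = 0; k < nk; ++k) {
    double Sr = 0.0, Si = 0.0;
    for (int a = 0; a < n; ++a) {
      double ph = pl.kx[k]*x[a] + pl.ky[k]*y[a] + pl.kz[k]*z[a];
      cs[a] = std::cos(ph); sn[a] = std::sin(ph);
      Sr += q[a]*cs[a]; Si += q[a]*sn[a];
    }
    double Ak = pl.Ak[k];
    e_recip += Ak * (Sr*Sr + Si*Si);
    double pref_f = prefac * (4.0*M_PI/V) * Ak; // includes half-space factor 2
    for (int a = 0; a < n; ++a) {
      // Im[ e^{i k r_a} S*(k) ] = sn[a]*Sr - cs[a]*Si
      double im = sn[a]*Sr - cs[a]*Si;
      double f = pref_f * q[a] * im;
      Fx[a] += f * pl.kx[k]; Fy[a] += f * pl.ky[k]; Fz[a] += f * pl.kz[k];
    }
  }
  e_recip *= (2.0*M_PI/V);
  for (int a = 0; a < n; ++a) e_self += q[a]*q[a];
  e_self *= -alpha / std::sqrt(M_PI);
  return prefac * (e_real + e_recip + e_self);
}

// [[Rcpp::export]]
List cpp_ewald(NumericMatrix pos, NumericVector q, double L,
               double alpha, int kmax, double rc, double prefac = 1.0) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), qq(n), Fx(n,0), Fy(n,0), Fz(n,0);
  for (int a = 0; a < n; ++a) { x[a]=pos(a,0); y[a]=pos(a,1); z[a]=pos(a,2); qq[a]=q[a]; }
  EwaldPlan pl = ewald_plan(L, alpha, kmax);
  double e = ewald_compute(x, y, z, qq, L, alpha, rc, pl, prefac, Fx, Fy, Fz);
  NumericMatrix F(n, 3);
  for (int a = 0; a < n; ++a) { F(a,0)=Fx[a]; F(a,1)=Fy[a]; F(a,2)=Fz[a]; }
  return List::create(_["energy"] = e, _["forces"] = F, _["n_kvec"] = (int)pl.kx.size());
}

// ---------------------------------------------------------------------------
// full force field: truncated-shifted LJ (+WCA), FENE bonds, Coulomb
// (shifted-force cutoff or Ewald)
// ---------------------------------------------------------------------------

struct FF {
  double eps_tt, eps_other, rc_tt, rc_other, k_fene, R0, prefac, rc_coul;
  int coul_method; // 0 none, 1 shifted-force cutoff, 2 ewald
  double alpha; int kmax;
  double ush_tt, ush_other; // LJ energy shifts at the cutoffs
};

struct SysArr {
  int n;
  std::vector<int> tail;          // 0/1 per bead
  std::vector<double> q;          // charge valence
  std::vector<int> charged;       // indices of charged beads
  std::vector<int> bi, bj;        // bonds (0-based)
};

static inline double ulj(double r2, double eps) {
  double ir2 = 1.0/r2, ir6 = ir2*ir2*ir2;
  return 4.0*eps*(ir6*ir6 - ir6);
}

// Verlet pair lists (LJ over all beads, Coulomb over charged beads),
// rebuilt at fixed global-step boundaries so that a run restarted at such a
// boundary reproduces the uninterrupted run bitwise
struct NeighborLists {
  std::vector<int> tt_i, tt_j; // tail-tail pairs (cutoff rc_tt)
  std::vector<int> oo_i, oo_j; // all other LJ pairs (cutoff rc_other)
  std::vector<int> c_i, c_j;   // charged pairs
  bool valid = false;
  double skin = 0.8;
};

static void build_lists(const std::vector<double>& x, const std::vector<double>& y,
                        const std::vector<double>& z, const SysArr& S,
                        const FF& ff, double L, NeighborLists& nl) {
  const int n = S.n;
  nl.tt_i.clear(); nl.tt_j.clear(); nl.oo_i.clear(); nl.oo_j.clear();
  nl.c_i.clear(); nl.c_j.clear();
  const double rl = std::max(ff.rc_tt, ff.rc_other) + nl.skin;
  const double rl2 = rl * rl;
  const double rtt2 = (ff.rc_tt + nl.skin) * (ff.rc_tt + nl.skin);
  const double roo2 = (ff.rc_other + nl.skin) * (ff.rc_other + nl.skin);
  auto classify = [&](int a, int b, double r2) {
    if (S.tail[a] && S.tail[b]) {
      if (r2 < rtt2) { nl.tt_i.push_back(a); nl.tt_j.push_back(b); }
    } else {
      if (r2 < roo2) { nl.oo_i.push_back(a); nl.oo_j.push_back(b); }
    }
  };
  int nc = (int)std::floor(L / rl);
  if (nc >= 3 && n > 64) {
    double cell = L / nc;
    std::vector<int> head(nc*nc*nc, -1), nxt(n, -1), ci(n);
    for (int a = 0; a < n; ++a) {
      double xa = x[a] - L*std::floor(x[a]/L);
      double ya = y[a] - L*std::floor(y[a]/L);
      double za = z[a] - L*std::floor(z[a]/L);
      int ix = std::min(nc-1, (int)std::floor(xa/cell));
      int iy = std::min(nc-1, (int)std::floor(ya/cell));
      int iz = std::min(nc-1, (int)std::floor(za/cell));
      int c = (ix*nc + iy)*nc + iz;
      ci[a] = c; nxt[a] = head[c]; head[c] = a;
    }
    for (int a = 0; a < n; ++a) {
      int ix = ci[a]/(nc*nc), iy = (ci[a]/nc)%nc, iz = ci[a]%nc;
      for (int ox = -1; ox <= 1; ++ox) for (int oy = -1; oy <= 1; ++oy) for (int oz = -1; oz <= 1; ++oz) {
        int jc = (((ix+ox+nc)%nc)*nc + (iy+oy+nc)%nc)*nc + (iz+oz+nc)%nc;
        for (int b = head[jc]; b != -1; b = nxt[b]) {
          if (b <= a) continue;
          double dx = mif(x[a]-x[b], L), dy = mif(y[a]-y[b], L), dz = mif(z[a]-z[b], L);
          double r2 = dx*dx + dy*dy + dz*dz;
          if (r2 < rl2) classify(a, b, r2);
        }
      }
    }
  } else {
    for (int a = 0; a < n; ++a) for (int b = a+1; b < n; ++b) {
      double dx = mif(x[a]-x[b], L), dy = mif(y[a]-y[b], L), dz = mif(z[a]-z[b], L);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 < rl2) classify(a, b, r2);
    }
  }
  if (ff.coul_method == 1) {
    double rcl = std::min(ff.rc_coul + nl.skin, L / 2.0);
    double rcl2 = rcl * rcl;
    const int m = (int)S.charged.size();
    for (int ia = 0; ia < m; ++ia) {
      int a = S.charged[ia];
      for (int ib = ia+1; ib < m; ++ib) {
        int b = S.charged[ib];
        double dx = mi(x[a]-x[b], L), dy = mi(y[a]-y[b], L), dz = mi(z[a]-z[b], L);
        if (dx*dx + dy*dy + dz*dz < rcl2) { nl.c_i.push_back(a); nl.c_j.push_back(b); }
      }
    }
  }
  nl.valid = true;
}

// forces + potential energy; returns false on FENE overstretch
static bool compute_forces(const std::vector<double>& x, const std::vector<double>& y,
                           const std::vector<double>& z, const SysArr& S, const FF& ff,
                           double L, const EwaldPlan* pl,
                           std::vector<double>& Fx, std::vector<double>& Fy,
                           std::vector<double>& Fz, double& epot,
                           const NeighborLists* nl = nullptr) {
  const int n = S.n;
  std::fill(Fx.begin(), Fx.end(), 0.0);
  std::fill(Fy.begin(), Fy.end(), 0.0);
  std::fill(Fz.begin(), Fz.end(), 0.0);
  epot = 0.0;
  const double rcmax = std::max(ff.rc_tt, ff.rc_other);
  const double rcmax2 = rcmax * rcmax;

  // ---- LJ through a cell list (fallback: all pairs) ----
  int nc = (int)std::floor(L / rcmax);
  auto lj_pair = [&](int a, int b) {
    double dx = mif(x[a]-x[b], L), dy = mif(y[a]-y[b], L), dz = mif(z[a]-z[b], L);
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 >= rcmax2) return;
    bool tt = S.tail[a] && S.tail[b];
    double rc = tt ? ff.rc_tt : ff.rc_other;
    if (r2 >= rc*rc) return;
    double eps = tt ? ff.eps_tt : ff.eps_other;
    double ush = tt ? ff.ush_tt : ff.ush_other;
    double ir2 = 1.0/r2, ir6 = ir2*ir2*ir2;
    epot += 4.0*eps*(ir6*ir6 - ir6) - ush;
    double fr = 24.0*eps*(2.0*ir6*ir6 - ir6)*ir2;
    Fx[a] += fr*dx; Fy[a] += fr*dy; Fz[a] += fr*dz;
    Fx[b] -= fr*dx; Fy[b] -= fr*dy; Fz[b] -= fr*dz;
  };
  if (nl != nullptr && nl->valid) {
    // typed pair kernels avoid per-pair type dispatch
    auto lj_typed = [&](int a, int b, double eps, double rc2v, double ush) {
      double dx = mif(x[a]-x[b], L), dy = mif(y[a]-y[b], L), dz = mif(z[a]-z[b], L);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= rc2v) return;
      double ir2 = 1.0/r2, ir6 = ir2*ir2*ir2;
      epot += 4.0*eps*(ir6*ir6 - ir6) - ush;
      double fr = 24.0*eps*(2.0*ir6*ir6 - ir6)*ir2;
      Fx[a] += fr*dx; Fy[a] += fr*dy; Fz[a] += fr*dz;
      Fx[b] -= fr*dx; Fy[b] -= fr*dy; Fz[b] -= fr*dz;
    };
    const double rctt2 = ff.rc_tt*ff.rc_tt, rcoo2 = ff.rc_other*ff.rc_other;
    for (size_t p = 0; p < nl->tt_i.size(); ++p)
      lj_typed(nl->tt_i[p], nl->tt_j[p], ff.eps_tt, rctt2, ff.ush_tt);
    for (size_t p = 0; p < nl->oo_i.size(); ++p)
      lj_typed(nl->oo_i[p], nl->oo_j[p], ff.eps_other, rcoo2, ff.ush_other);
  } else if (nc >= 3 && n > 64) {
    // linked-cell list: head[cell] -> first bead, nxt[bead] -> next in cell
    double cell = L / nc;
    static thread_local std::vector<int> head, nxt, ci;
    head.assign(nc*nc*nc, -1);
    nxt.assign(n, -1);
    ci.assign(n, 0);
    for (int a = 0; a < n; ++a) {
      double xa = x[a] - L*std::floor(x[a]/L);
      double ya = y[a] - L*std::floor(y[a]/L);
      double za = z[a] - L*std::floor(z[a]/L);
      int ix = std::min(nc-1, (int)std::floor(xa/cell));
      int iy = std::min(nc-1, (int)std::floor(ya/cell));
      int iz = std::min(nc-1, (int)std::floor(za/cell));
      int c = (ix*nc + iy)*nc + iz;
      ci[a] = c;
      nxt[a] = head[c];
      head[c] = a;
    }
    for (int a = 0; a < n; ++a) {
      int ix = ci[a]/(nc*nc), iy = (ci[a]/nc)%nc, iz = ci[a]%nc;
      for (int ox = -1; ox <= 1; ++ox) for (int oy = -1; oy <= 1; ++oy) for (int oz = -1; oz <= 1; ++oz) {
        int jc = (((ix+ox+nc)%nc)*nc + (iy+oy+nc)%nc)*nc + (iz+oz+nc)%nc;
        for (int b = head[jc]; b != -1; b = nxt[b]) if (b > a) lj_pair(a, b);
      }
    }
  } else {
    for (int a = 0; a < n; ++a) for (int b = a+1; b < n; ++b) lj_pair(a, b);
  }

  // ---- FENE bonds ----
  const double R02 = ff.R0*ff.R0;
  for (size_t m = 0; m < S.bi.size(); ++m) {
    int a = S.bi[m], b = S.bj[m];
    double dx = mif(x[a]-x[b], L), dy = mif(y[a]-y[b], L), dz = mif(z[a]-z[b], L);
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 >= R02) return false; // overstretch
    double denom = 1.0 - r2/R02;
    epot += -0.5*ff.k_fene*R02*std::log(denom);
    double fr = -ff.k_fene/denom;
    Fx[a] += fr*dx; Fy[a] += fr*dy; Fz[a] += fr*dz;
    Fx[b] -= fr*dx; Fy[b] -= fr*dy; Fz[b] -= fr*dz;
  }

  // ---- Coulomb ----
  if (ff.coul_method == 1) {
    // shifted-force truncation: U(r) = C qq (1/r - 1/rc + (r - rc)/rc^2)
    const double rc = ff.rc_coul, rc2i = 1.0/(rc*rc);
    auto coul_pair = [&](int a, int b) {
      double dx = mif(x[a]-x[b], L), dy = mif(y[a]-y[b], L), dz = mif(z[a]-z[b], L);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= rc*rc) return;
      double r = std::sqrt(r2);
      double C = ff.prefac * S.q[a]*S.q[b];
      epot += C*(1.0/r - 1.0/rc + (r - rc)*rc2i);
      double fr = C*(1.0/r2 - rc2i)/r;
      Fx[a] += fr*dx; Fy[a] += fr*dy; Fz[a] += fr*dz;
      Fx[b] -= fr*dx; Fy[b] -= fr*dy; Fz[b] -= fr*dz;
    };
    if (nl != nullptr && nl->valid) {
      const size_t np = nl->c_i.size();
      for (size_t p = 0; p < np; ++p) coul_pair(nl->c_i[p], nl->c_j[p]);
    } else {
      const int m = (int)S.charged.size();
      for (int ia = 0; ia < m; ++ia)
        for (int ib = ia+1; ib < m; ++ib)
          coul_pair(S.charged[ia], S.charged[ib]);
    }
  } else if (ff.coul_method == 2 && pl != nullptr) {
    const int m = (int)S.charged.size();
    std::vector<double> cx(m), cy(m), cz(m), cq(m), fx(m,0), fy(m,0), fz(m,0);
    for (int ia = 0; ia < m; ++ia) {
      int a = S.charged[ia];
      cx[ia]=x[a]; cy[ia]=y[a]; cz[ia]=z[a]; cq[ia]=S.q[a];
    }
    epot += ewald_compute(cx, cy, cz, cq, L, ff.alpha, ff.rc_coul, *pl, ff.prefac, fx, fy, fz);
    for (int ia = 0; ia < m; ++ia) {
      int a = S.charged[ia];
      Fx[a] += fx[ia]; Fy[a] += fy[ia]; Fz[a] += fz[ia];
    }
  }
  return true;
}

static FF make_ff(List params) {
  FF ff;
  ff.eps_tt = as<double>(params["eps_tt"]);
  ff.eps_other = as<double>(params["eps_other"]);
  ff.rc_tt = as<double>(params["rc_lj_tt"]);
  ff.rc_other = as<double>(params["rc_lj_other"]);
  ff.k_fene = as<double>(params["k_fene"]);
  ff.R0 = as<double>(params["R0"]);
  ff.prefac = as<double>(params["lambda_B_star"]);
  ff.rc_coul = as<double>(params["rc_coul"]);
  ff.coul_method = as<int>(params["coul_method"]);
  ff.alpha = as<double>(params["alpha"]);
  ff.kmax = as<int>(params["kmax"]);
  ff.ush_tt = ulj(ff.rc_tt*ff.rc_tt, ff.eps_tt);
  ff.ush_other = ulj(ff.rc_other*ff.rc_other, ff.eps_other);
  return ff;
}

static SysArr make_sys(int n, IntegerVector is_tail, NumericVector q, IntegerMatrix bonds) {
  SysArr S; S.n = n;
  S.tail.resize(n); S.q.resize(n);
  for (int a = 0; a < n; ++a) {
    S.tail[a] = is_tail[a]; S.q[a] = q[a];
    if (q[a] != 0.0) S.charged.push_back(a);
  }
  for (int m = 0; m < bonds.nrow(); ++m) {
    S.bi.push_back(bonds(m,0) - 1);
    S.bj.push_back(bonds(m,1) - 1);
  }
  return S;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, double L, IntegerVector is_tail,
                NumericVector q, IntegerMatrix bonds, List params) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), Fx(n), Fy(n), Fz(n);
  for (int a = 0; a < n; ++a) {
    x[a] = pos(a,0) - L*std::floor(pos(a,0)/L);
    y[a] = pos(a,1) - L*std::floor(pos(a,1)/L);
    z[a] = pos(a,2) - L*std::floor(pos(a,2)/L);
  }
  FF ff = make_ff(params);
  SysArr S = make_sys(n, is_tail, q, bonds);
  EwaldPlan pl;
  if (ff.coul_method == 2) pl = ewald_plan(L, ff.alpha, ff.kmax);
  double epot = 0.0;
  bool ok = compute_forces(x, y, z, S, ff, L, ff.coul_method == 2 ? &pl : nullptr,
                           Fx, Fy, Fz, epot);
  if (!ok) stop("FENE bond overstretched (r >= R0)");
  NumericMatrix F(n, 3);
  for (int a = 0; a < n; ++a) { F(a,0)=Fx[a]; F(a,1)=Fy[a]; F(a,2)=Fz[a]; }
  return List::create(_["forces"] = F, _["epot"] = epot);
}

// ---------------------------------------------------------------------------
// thermostat noise: xoshiro256++ with Box-Muller, seeded deterministically
// from R's RNG stream; the generator state travels with the trajectory so
// a restarted run continues the exact noise sequence
// ---------------------------------------------------------------------------

struct Xo {
  uint64_t s[4];
  double spare = 0.0;
  bool has_spare = false;
};

static inline uint64_t rotl64(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

static inline uint64_t xo_next(Xo& g) {
  uint64_t r = rotl64(g.s[0] + g.s[3], 23) + g.s[0];
  uint64_t t = g.s[1] << 17;
  g.s[2] ^= g.s[0]; g.s[3] ^= g.s[1]; g.s[1] ^= g.s[2]; g.s[0] ^= g.s[3];
  g.s[2] ^= t; g.s[3] = rotl64(g.s[3], 45);
  return r;
}

static inline double xo_unif(Xo& g) { return (xo_next(g) >> 11) * 0x1.0p-53; }

static inline double xo_norm(Xo& g) {
  if (g.has_spare) { g.has_spare = false; return g.spare; }
  double u1 = xo_unif(g);
  while (u1 <= 0.0) u1 = xo_unif(g);
  double u2 = xo_unif(g);
  double r = std::sqrt(-2.0 * std::log(u1)), th = 2.0 * M_PI * u2;
  g.spare = r * std::sin(th); g.has_spare = true;
  return r * std::cos(th);
}

static uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// state <-> R vector: each 64-bit word as two exact 32-bit doubles
static NumericVector xo_pack(const Xo& g) {
  NumericVector v(10);
  for (int i = 0; i < 4; ++i) {
    v[2*i] = (double)(g.s[i] & 0xffffffffULL);
    v[2*i+1] = (double)(g.s[i] >> 32);
  }
  v[8] = g.spare; v[9] = g.has_spare ? 1.0 : 0.0;
  return v;
}

static Xo xo_unpack(NumericVector v) {
  Xo g;
  for (int i = 0; i < 4; ++i) {
    g.s[i] = (uint64_t)v[2*i] | ((uint64_t)v[2*i+1] << 32);
  }
  g.spare = v[8]; g.has_spare = v[9] != 0.0;
  return g;
}

// ---------------------------------------------------------------------------
// Langevin dynamics: BAOAB splitting of the underdamped Langevin equation.
// With gamma = 0 and no noise this reduces exactly to velocity Verlet (NVE).
// Noise seeding is drawn from R's RNG, so runs reproduce under set.seed().
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos, NumericMatrix vel, double L,
                      IntegerVector is_tail, NumericVector q, IntegerMatrix bonds,
                      List params, int nsteps, int stride, double limit = 0.0,
                      int step0 = 0,
                      Nullable<NumericVector> rng_state = R_NilValue) {
  const int n = pos.nrow();
  const double dt = as<double>(params["dt_star"]);
  const double gamma = as<double>(params["gamma_star"]);
  const double Tstar = as<double>(params["T_star"]);
  const double mass = as<double>(params["mass"]);
  FF ff = make_ff(params);
  SysArr S = make_sys(n, is_tail, q, bonds);
  EwaldPlan pl;
  if (ff.coul_method == 2) pl = ewald_plan(L, ff.alpha, ff.kmax);
  const EwaldPlan* plp = ff.coul_method == 2 ? &pl : nullptr;

  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n), Fx(n), Fy(n), Fz(n);
  for (int a = 0; a < n; ++a) {
    x[a]=pos(a,0); y[a]=pos(a,1); z[a]=pos(a,2);
    vx[a]=vel(a,0); vy[a]=vel(a,1); vz[a]=vel(a,2);
  }
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(Tstar * (1.0 - c1*c1) / mass);
  const double idm = 1.0 / mass;

  // pair lists are rebuilt at fixed global-step boundaries (every K steps
  // counted from step 0 of the whole run) so that restarting at a boundary
  // reproduces an uninterrupted run bitwise; the tighter interval under a
  // displacement cap keeps the skin safe during push-off relaxation
  NeighborLists nl;
  const int K = (limit > 0.0) ? 4 : 20;
  auto rewrap = [&]() {
    for (int a = 0; a < n; ++a) {
      x[a] -= L*std::floor(x[a]/L);
      y[a] -= L*std::floor(y[a]/L);
      z[a] -= L*std::floor(z[a]/L);
    }
  };
  rewrap();
  build_lists(x, y, z, S, ff, L, nl);
  double epot = 0.0;
  if (!compute_forces(x, y, z, S, ff, L, plp, Fx, Fy, Fz, epot, &nl))
    stop("FENE bond overstretched in initial configuration");

  int nrec = nsteps / std::max(stride, 1) + 1;
  List frames(nrec);
  IntegerVector rec_steps(nrec);
  NumericVector rec_pe(nrec), rec_ke(nrec), rec_T(nrec);
  int irec = 0;
  auto record = [&](int step) {
    NumericMatrix fr(n, 3);
    double ke = 0.0;
    for (int a = 0; a < n; ++a) {
      fr(a,0) = x[a] - L*std::floor(x[a]/L);
      fr(a,1) = y[a] - L*std::floor(y[a]/L);
      fr(a,2) = z[a] - L*std::floor(z[a]/L);
      ke += 0.5*mass*(vx[a]*vx[a] + vy[a]*vy[a] + vz[a]*vz[a]);
    }
    frames[irec] = fr;
    rec_steps[irec] = step0 + step;
    rec_pe[irec] = epot; rec_ke[irec] = ke;
    rec_T[irec] = 2.0*ke / (3.0*n);
    ++irec;
  };
  record(0);

  Xo gen;
  if (rng_state.isNotNull() && NumericVector(rng_state).size() == 10) {
    gen = xo_unpack(NumericVector(rng_state));
  } else {
    GetRNGstate();
    uint64_t seed = (uint64_t)(unif_rand() * 4294967296.0) ^
                    ((uint64_t)(unif_rand() * 4294967296.0) << 32);
    PutRNGstate();
    for (int i = 0; i < 4; ++i) gen.s[i] = splitmix64(seed);
  }
  bool bad = false; int bad_step = -1; bool nan_seen = false;
  for (int step = 1; step <= nsteps; ++step) {
    double hdt = 0.5*dt;
    for (int a = 0; a < n; ++a) { // B
      vx[a] += hdt*Fx[a]*idm; vy[a] += hdt*Fy[a]*idm; vz[a] += hdt*Fz[a]*idm;
    }
    if (limit > 0.0) { // cap speeds during push-off relaxation
      double vmax = limit / dt;
      for (int a = 0; a < n; ++a) {
        double s = std::sqrt(vx[a]*vx[a]+vy[a]*vy[a]+vz[a]*vz[a]);
        if (s > vmax) { double f = vmax/s; vx[a]*=f; vy[a]*=f; vz[a]*=f; }
      }
    }
    for (int a = 0; a < n; ++a) { // A
      x[a] += hdt*vx[a]; y[a] += hdt*vy[a]; z[a] += hdt*vz[a];
    }
    if (gamma > 0.0) { // O
      for (int a = 0; a < n; ++a) {
        vx[a] = c1*vx[a] + c2*xo_norm(gen);
        vy[a] = c1*vy[a] + c2*xo_norm(gen);
        vz[a] = c1*vz[a] + c2*xo_norm(gen);
      }
    }
    for (int a = 0; a < n; ++a) { // A
      x[a] += hdt*vx[a]; y[a] += hdt*vy[a]; z[a] += hdt*vz[a];
    }
    if ((step0 + step) % K == 0) { rewrap(); build_lists(x, y, z, S, ff, L, nl); }
    if (!compute_forces(x, y, z, S, ff, L, plp, Fx, Fy, Fz, epot, &nl)) {
      bad = true; bad_step = step; break;
    }
    for (int a = 0; a < n; ++a) { // B
      vx[a] += hdt*Fx[a]*idm; vy[a] += hdt*Fy[a]*idm; vz[a] += hdt*Fz[a]*idm;
    }
    if (!std::isfinite(x[0]) || !std::isfinite(epot)) {
      nan_seen = true; bad_step = step; break;
    }
    if (stride > 0 && step % stride == 0) record(step);
  }
  if (bad) stop("FENE bond overstretched (r >= R0) at step %d; reduce dt or relax first", bad_step);
  if (nan_seen) stop("non-finite coordinates at step %d; simulation aborted", bad_step);

  NumericMatrix fpos(n,3), fvel(n,3);
  for (int a = 0; a < n; ++a) {
    fpos(a,0)=x[a]; fpos(a,1)=y[a]; fpos(a,2)=z[a];
    fvel(a,0)=vx[a]; fvel(a,1)=vy[a]; fvel(a,2)=vz[a];
  }
  // trim record vectors to what was filled
  if (irec < nrec) {
    frames = frames[Range(0, irec-1)];
    rec_steps = rec_steps[Range(0, irec-1)];
    rec_pe = rec_pe[Range(0, irec-1)];
    rec_ke = rec_ke[Range(0, irec-1)];
    rec_T = rec_T[Range(0, irec-1)];
  }
  return List::create(
    _["frames"] = frames, _["steps"] = rec_steps,
    _["pe"] = rec_pe, _["ke"] = rec_ke, _["temperature"] = rec_T,
    _["final_pos"] = fpos, _["final_vel"] = fvel,
    _["rng_state"] = xo_pack(gen)
  );
}
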