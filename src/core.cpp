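// Simulation core: planar 7-segment musculoskeletal plant, Hill-type
// muscles, delayed reflex controller, and the full episode loop.
//
// Generalized coordinates q (9): hip x, hip y, trunk angle (CCW, forward
// lean negative), then per leg hip/knee/ankle in flexion(dorsiflexion)-
// positive convention.  Absolute segment angles are linear in q, so the
// angular Jacobian is constant; COM/point Jacobians are assembled from
// chains of fixed-length vectors, each a function of one absolute angle.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NQ = 9;

struct Plant {
  // trunk (head+arms+torso), thigh, shank: mass, length, com offset, inertia
  double m_t, L_t, c_t, I_t;
  double m_th, L_th, c_th, I_th;
  double m_sh, L_sh, c_sh, I_sh;
  // foot: ankle sits h_ank above the sole, a_heel behind / b_toe in front
  double m_ft, I_ft, a_heel, b_toe, h_ank, fcx, fcy;
  // contact
  double k_n, b_n, mu, v_reg;
  double g;
  double total_mass() const { return m_t + 2.0 * (m_th + m_sh + m_ft); }
};

static Plant plant_from_list(const List& pl) {
  Plant p;
  p.m_t = pl["m_trunk"];  p.L_t = pl["l_trunk"];  p.c_t = pl["c_trunk"];  p.I_t = pl["i_trunk"];
  p.m_th = pl["m_thigh"]; p.L_th = pl["l_thigh"]; p.c_th = pl["c_thigh"]; p.I_th = pl["i_thigh"];
  p.m_sh = pl["m_shank"]; p.L_sh = pl["l_shank"]; p.c_sh = pl["c_shank"]; p.I_sh = pl["i_shank"];
  p.m_ft = pl["m_foot"];  p.I_ft = pl["i_foot"];
  p.a_heel = pl["a_heel"]; p.b_toe = pl["b_toe"]; p.h_ank = pl["h_ankle"];
  p.fcx = pl["foot_cx"];  p.fcy = pl["foot_cy"];
  p.k_n = pl["contact_stiffness"]; p.b_n = pl["contact_damping"];
  p.mu = pl["friction_mu"]; p.v_reg = pl["friction_vreg"];
  p.g = pl["gravity"];
  return p;
}

// absolute angle indices: 0 trunk, 1..3 left thigh/shank/foot, 4..6 right
struct Kin {
  double alpha[7], ad[7];        // absolute angles and rates
  double sa[7], ca[7];
  // S: dalpha/dq, constant sparse; stored dense 7 x 9
  double S[7][NQ];
};

static void kin_compute(const Plant& p, const double* q, const double* qd, Kin& k) {
  (void)p;
  for (int i = 0; i < 7; ++i)
    for (int j = 0; j < NQ; ++j) k.S[i][j] = 0.0;
  k.S[0][2] = 1.0;
  for (int leg = 0; leg < 2; ++leg) {
    int off = 3 + 3 * leg;  // q index of hip
    int a0 = 1 + 3 * leg;   // alpha index of thigh
    // thigh
    k.S[a0][2] = 1.0; k.S[a0][off] = 1.0;
    // shank
    k.S[a0+1][2] = 1.0; k.S[a0+1][off] = 1.0; k.S[a0+1][off+1] = -1.0;
    // foot
    k.S[a0+2][2] = 1.0; k.S[a0+2][off] = 1.0; k.S[a0+2][off+1] = -1.0; k.S[a0+2][off+2] = 1.0;
  }
  k.alpha[0] = q[2];
  k.ad[0] = qd[2];
  for (int leg = 0; leg < 2; ++leg) {
    int off = 3 + 3 * leg, a0 = 1 + 3 * leg;
    k.alpha[a0]     = q[2] + q[off];
    k.alpha[a0 + 1] = q[2] + q[off] - q[off + 1];
    k.alpha[a0 + 2] = q[2] + q[off] - q[off + 1] + q[off + 2];
    k.ad[a0]     = qd[2] + qd[off];
    k.ad[a0 + 1] = qd[2] + qd[off] - qd[off + 1];
    k.ad[a0 + 2] = qd[2] + qd[off] - qd[off + 1] + qd[off + 2];
  }
  for (int i = 0; i < 7; ++i) { k.sa[i] = std::sin(k.alpha[i]); k.ca[i] = std::cos(k.alpha[i]); }
}

// chain vector attached to absolute angle a: local coords (lx, ly) rotated by alpha
struct CVec { int a; double lx, ly; };

// world components of a chain vector
static inline void cvec_world(const Kin& k, const CVec& v, double& wx, double& wy) {
  wx = v.lx * k.ca[v.a] - v.ly * k.sa[v.a];
  wy = v.lx * k.sa[v.a] + v.ly * k.ca[v.a];
}

// point = hip + sum of chain vectors; fills position, velocity, Jacobian (2 x NQ),
// and bias acceleration (qdd = 0 term)
struct PointK {
  double x, y, vx, vy;
  double Jx[NQ], Jy[NQ];
  double bx, by;
};

static void point_kin(const Kin& k, const double* q, const double* qd,
                      const CVec* chain, int nchain, PointK& out) {
  out.x = q[0]; out.y = q[1];
  out.vx = qd[0]; out.vy = qd[1];
  for (int j = 0; j < NQ; ++j) { out.Jx[j] = 0.0; out.Jy[j] = 0.0; }
  out.Jx[0] = 1.0; out.Jy[1] = 1.0;
  out.bx = 0.0; out.by = 0.0;
  for (int c = 0; c < nchain; ++c) {
    double wx, wy; cvec_world(k, chain[c], wx, wy);
    int a = chain[c].a;
    out.x += wx; out.y += wy;
    // d/dalpha of (wx, wy) is rot90 = (-wy, wx)
    out.vx += -wy * k.ad[a];
    out.vy +=  wx * k.ad[a];
    for (int j = 0; j < NQ; ++j) {
      if (k.S[a][j] != 0.0) {
        out.Jx[j] += -wy * k.S[a][j];
        out.Jy[j] +=  wx * k.S[a][j];
      }
    }
    out.bx += -k.ad[a] * k.ad[a] * wx;
    out.by += -k.ad[a] * k.ad[a] * wy;
  }
}

// trunk axis direction u(alpha) = (-sin, cos): chain vector with local (0, len)
// leg direction  d(alpha) = (sin, -cos): chain vector with local (0, -len)

// Bodies for dynamics: chains to COM
struct BodyDef { double m, I; CVec chain[4]; int n; int aidx; };

static void build_bodies(const Plant& p, BodyDef* B) {
  // 0 trunk
  B[0].m = p.m_t; B[0].I = p.I_t; B[0].n = 1; B[0].aidx = 0;
  B[0].chain[0] = {0, 0.0, p.c_t};
  for (int leg = 0; leg < 2; ++leg) {
    int a0 = 1 + 3 * leg; int b0 = 1 + 3 * leg;
    B[b0].m = p.m_th; B[b0].I = p.I_th; B[b0].n = 1; B[b0].aidx = a0;
    B[b0].chain[0] = {a0, 0.0, -p.c_th};
    B[b0+1].m = p.m_sh; B[b0+1].I = p.I_sh; B[b0+1].n = 2; B[b0+1].aidx = a0 + 1;
    B[b0+1].chain[0] = {a0, 0.0, -p.L_th};
    B[b0+1].chain[1] = {a0+1, 0.0, -p.c_sh};
    B[b0+2].m = p.m_ft; B[b0+2].I = p.I_ft; B[b0+2].n = 3; B[b0+2].aidx = a0 + 2;
    B[b0+2].chain[0] = {a0, 0.0, -p.L_th};
    B[b0+2].chain[1] = {a0+1, 0.0, -p.L_sh};
    B[b0+2].chain[2] = {a0+2, p.fcx, -p.fcy};
  }
}

// contact points: heel and toe of each foot (leg 0 left, 1 right)
static void contact_chain(const Plant& p, int leg, bool heel, CVec* chain) {
  int a0 = 1 + 3 * leg;
  chain[0] = {a0, 0.0, -p.L_th};
  chain[1] = {a0 + 1, 0.0, -p.L_sh};
  chain[2] = {a0 + 2, heel ? -p.a_heel : p.b_toe, -p.h_ank};
}

struct ContactForce { double fx, fy; };

// spring-damper normal + regularized Coulomb friction; platform top at y = 0
static ContactForce contact_force(const Plant& p, const PointK& pt,
                                  double plat_v) {
  ContactForce f{0.0, 0.0};
  double pen = -pt.y;
  if (pen <= 0.0) return f;
  double pen_rate = -pt.vy;
  double fn = pen * (p.k_n + p.b_n * pen_rate);
  if (fn < 0.0) fn = 0.0;
  double vrel = pt.vx - plat_v;
  double ft = -p.mu * fn * std::tanh(vrel / p.v_reg);
  f.fx = ft; f.fy = fn;
  return f;
}

// 9x9 symmetric positive-definite solve via Cholesky (hand-rolled: the mass
// matrix is small and this sits in the innermost loop)
static bool chol_solve9(double A[NQ][NQ], const double* b, double* x) {
  double L[NQ][NQ];
  for (int i = 0; i < NQ; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i][j];
      for (int k = 0; k < j; ++k) s -= L[i][k] * L[j][k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i][i] = std::sqrt(s);
      } else {
        L[i][j] = s / L[j][j];
      }
    }
  }
  double y[NQ];
  for (int i = 0; i < NQ; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i][k] * y[k];
    y[i] = s / L[i][i];
  }
  for (int i = NQ - 1; i >= 0; --i) {
    double s = y[i];
    for (int k = i + 1; k < NQ; ++k) s -= L[k][i] * x[k];
    x[i] = s / L[i][i];
  }
  return true;
}

// full plant dynamics: returns qdd; optionally accumulates contact info
struct DynScratch {
  BodyDef B[7];
  arma::mat Msk;       // constant rotational part sum I * S^T S
  bool init = false;
};

// per-body nonzero Jacobian columns (base x, y, trunk angle + leg joints)
static const int BODY_COLS[7][6] = {
  {0, 1, 2, -1, -1, -1},
  {0, 1, 2, 3, -1, -1}, {0, 1, 2, 3, 4, -1}, {0, 1, 2, 3, 4, 5},
  {0, 1, 2, 6, -1, -1}, {0, 1, 2, 6, 7, -1}, {0, 1, 2, 6, 7, 8}
};

static void sc_init(const Plant& p, DynScratch& sc) {
  if (sc.init) return;
  build_bodies(p, sc.B);
  sc.Msk.zeros(NQ, NQ);
  double dummyq[NQ] = {0}, dummyqd[NQ] = {0};
  Kin k0; kin_compute(p, dummyq, dummyqd, k0);
  for (int b = 0; b < 7; ++b) {
    int a = sc.B[b].aidx;
    for (int i = 0; i < NQ; ++i)
      for (int j = 0; j < NQ; ++j)
        sc.Msk(i, j) += sc.B[b].I * k0.S[a][i] * k0.S[a][j];
  }
  sc.init = true;
}

// assemble with precomputed per-body point kinematics (one pass per step)
static void dyn_qdd_pk(const Plant& p, DynScratch& sc, const Kin& k,
                       const double* q, const double* qd, const PointK* bodypk,
                       const double* tau6, double plat_v, bool contact_on,
                       double* qdd_out, double* grf_y = nullptr,
                       double* grf_x = nullptr, double* cforces = nullptr) {
  double M[NQ][NQ], Q[NQ];
  for (int i = 0; i < NQ; ++i) {
    Q[i] = 0.0;
    for (int j = 0; j < NQ; ++j) M[i][j] = sc.Msk(i, j);
  }
  for (int b = 0; b < 7; ++b) {
    const BodyDef& bd = sc.B[b];
    const PointK& pk = bodypk[b];
    for (int ci = 0; ci < 6; ++ci) {
      int i = BODY_COLS[b][ci];
      if (i < 0) break;
      for (int cj = ci; cj < 6; ++cj) {
        int j = BODY_COLS[b][cj];
        if (j < 0) break;
        M[i][j] += bd.m * (pk.Jx[i] * pk.Jx[j] + pk.Jy[i] * pk.Jy[j]);
      }
      Q[i] += pk.Jy[i] * (-bd.m * p.g) - bd.m * (pk.Jx[i] * pk.bx + pk.Jy[i] * pk.by);
    }
  }
  for (int i = 0; i < NQ; ++i)
    for (int j = 0; j < i; ++j) M[i][j] = M[j][i];
  for (int leg = 0; leg < 2; ++leg)
    for (int j = 0; j < 3; ++j) Q[3 + 3 * leg + j] += tau6[3 * leg + j];
  double gy = 0.0, gx = 0.0;
  if (contact_on) {
    CVec chain[3];
    PointK pk;
    int ci = 0;
    for (int leg = 0; leg < 2; ++leg) {
      for (int h = 0; h < 2; ++h) {
        contact_chain(p, leg, h == 0, chain);
        point_kin(k, q, qd, chain, 3, pk);
        ContactForce f = contact_force(p, pk, plat_v);
        gy += f.fy; gx += f.fx;
        if (cforces) { cforces[2 * ci] = f.fx; cforces[2 * ci + 1] = f.fy; }
        ++ci;
        if (f.fx != 0.0 || f.fy != 0.0)
          for (int i = 0; i < NQ; ++i)
            Q[i] += pk.Jx[i] * f.fx + pk.Jy[i] * f.fy;
      }
    }
  }
  if (grf_y) *grf_y = gy;
  if (grf_x) *grf_x = gx;
  if (!chol_solve9(M, Q, qdd_out))
    stop("singular mass matrix");
}

static void dyn_qdd(const Plant& p, DynScratch& sc, const double* q, const double* qd,
                    const double* tau6,      // hipL kneeL ankL hipR kneeR ankR
                    double plat_v, bool contact_on,
                    double* qdd_out, double* grf_y = nullptr, double* grf_x = nullptr,
                    double* cforces = nullptr /* 8: fx,fy per point h/t L, h/t R */) {
  Kin k;
  kin_compute(p, q, qd, k);
  sc_init(p, sc);
  PointK bodypk[7];
  for (int b = 0; b < 7; ++b)
    point_kin(k, q, qd, sc.B[b].chain, sc.B[b].n, bodypk[b]);
  dyn_qdd_pk(p, sc, k, q, qd, bodypk, tau6, plat_v, contact_on,
             qdd_out, grf_y, grf_x, cforces);
}

static void com_position(const Plant& p, DynScratch& sc, const double* q,
                         double& cx, double& cy) {
  double qd0[NQ] = {0};
  Kin k; kin_compute(p, q, qd0, k);
  sc_init(p, sc);
  double mx = 0.0, my = 0.0, mtot = 0.0;
  PointK pk;
  for (int b = 0; b < 7; ++b) {
    point_kin(k, q, qd0, sc.B[b].chain, sc.B[b].n, pk);
    mx += sc.B[b].m * pk.x; my += sc.B[b].m * pk.y; mtot += sc.B[b].m;
  }
  cx = mx / mtot; cy = my / mtot;
}

// ---------------------------------------------------------------- muscles --

struct MusPar {
  double fmax, lopt, lslack, pen, eps_ref, vmax, w, fvN, fvK, dc, tact, tdeact;
  // geometry: signed moment arm (0 = joint not spanned), reference angle, shape
  double r[3], phi[3]; int shape[3];
};

static MusPar muspar_from_row(const NumericMatrix& m, int i) {
  MusPar mp;
  mp.fmax = m(i, 0); mp.lopt = m(i, 1); mp.lslack = m(i, 2); mp.pen = m(i, 3);
  mp.eps_ref = m(i, 4); mp.vmax = m(i, 5); mp.w = m(i, 6);
  mp.fvN = m(i, 7); mp.fvK = m(i, 8); mp.dc = m(i, 9);
  mp.tact = m(i, 10); mp.tdeact = m(i, 11);
  for (int j = 0; j < 3; ++j) {
    mp.r[j] = m(i, 12 + 3 * j);
    mp.phi[j] = m(i, 13 + 3 * j);
    mp.shape[j] = (int)m(i, 14 + 3 * j);
  }
  return mp;
}

// musculotendon length at joint angles (hip, knee, ankle), reference posture = 0
static double mtu_length(const MusPar& mp, const double* th) {
  double l = mp.lslack + mp.pen * mp.lopt;
  for (int j = 0; j < 3; ++j) {
    if (mp.r[j] == 0.0) continue;
    if (mp.shape[j] == 0) l += -mp.r[j] * th[j];
    else l += -mp.r[j] * (std::sin(th[j] - mp.phi[j]) - std::sin(-mp.phi[j]));
  }
  return l;
}

static double moment_arm(const MusPar& mp, int j, double th) {
  if (mp.r[j] == 0.0) return 0.0;
  if (mp.shape[j] == 0) return mp.r[j];
  return mp.r[j] * std::cos(th - mp.phi[j]);
}

static double see_force(const MusPar& mp, double l_see) {
  if (l_see <= mp.lslack) return 0.0;
  double e = (l_see - mp.lslack) / (mp.lslack * mp.eps_ref);
  return mp.fmax * e * e;
}

static double fl_curve(const MusPar& mp, double lce) {
  static const double LOG_RESIDUAL = std::log(0.05);
  double x = std::fabs((lce - mp.lopt) / (mp.lopt * mp.w));
  return std::exp(LOG_RESIDUAL * x * x * x);
}

static double fv_curve(const MusPar& mp, double vbar) {
  if (vbar < -1.0) return 0.0;
  if (vbar <= 0.0) return (1.0 + vbar) / (1.0 - mp.fvK * vbar);
  return mp.fvN - (mp.fvN - 1.0) / (1.0 + 7.56 * mp.fvK * vbar);
}

static double pe_force(const MusPar& mp, double lce) {
  if (lce <= mp.lopt) return 0.0;
  double x = (lce - mp.lopt) / (mp.lopt * mp.w);
  return mp.fmax * x * x;
}

static double be_force(const MusPar& mp, double lce) {
  double lmin = mp.lopt * (1.0 - mp.w);
  if (lce >= lmin) return 0.0;
  double x = (lmin - lce) / (mp.lopt * mp.w * 0.5);
  return mp.fmax * x * x;
}

// solve CE velocity (vbar, units of lopt*vmax per second normalized to [-1, 1])
// from force balance  pen*(a Fmax fl fv(vbar) + FPE + dc Fmax vbar - FBE) = FSEE
struct CERate { double vbar; double resid; int clipped; };

static CERate solve_vce(const MusPar& mp, double lce, double act, double lmtu,
                        double hint = 0.0) {
  double l_see = lmtu - mp.pen * lce;
  double fsee = see_force(mp, l_see);
  double need = fsee / mp.pen;
  double afl = act * mp.fmax * fl_curve(mp, lce);
  double fpe = pe_force(mp, lce), fbe = be_force(mp, lce);
  double damp = mp.dc * mp.fmax;
  double rest = fpe - fbe - need;
  auto g = [&](double v) {
    return afl * fv_curve(mp, v) + damp * v + rest;
  };
  // On each force-velocity branch the balance g(v) = 0 multiplies out to a
  // quadratic in v (fv is a Moebius function of v), so the root is closed
  // form; the Newton loop below only serves as a safeguarded fallback.
  auto quad_root = [](double A, double B, double C, double lo, double hi,
                      double& root) {
    if (std::fabs(A) < 1e-300) {
      if (std::fabs(B) < 1e-300) return false;
      root = -C / B;
      return root >= lo && root <= hi;
    }
    double disc = B * B - 4.0 * A * C;
    if (disc < 0.0) return false;
    double sq = std::sqrt(disc);
    double q = -0.5 * (B + (B >= 0.0 ? sq : -sq));
    double r1 = q / A;
    double r2 = (q != 0.0) ? C / q : r1;
    if (r1 >= lo && r1 <= hi) { root = r1; return true; }
    if (r2 >= lo && r2 <= hi) { root = r2; return true; }
    return false;
  };
  // residual and analytic derivative in one pass (fv is piecewise rational)
  auto gdg = [&](double v, double& gv, double& dv) {
    double fv, dfv;
    if (v < -1.0) { fv = 0.0; dfv = 0.0; }
    else if (v <= 0.0) {
      double inv = 1.0 / (1.0 - mp.fvK * v);
      fv = (1.0 + v) * inv;
      dfv = (1.0 + mp.fvK) * inv * inv;
    } else {
      double c = 7.56 * mp.fvK, inv = 1.0 / (1.0 + c * v);
      fv = mp.fvN - (mp.fvN - 1.0) * inv;
      dfv = (mp.fvN - 1.0) * c * inv * inv;
    }
    gv = afl * fv + damp * v + rest;
    dv = afl * dfv + damp;
  };
  double lo = -1.0, hi = 1.0;
  double glo = g(lo), ghi = g(hi);
  CERate out{0.0, 0.0, 0};
  if (glo >= 0.0) { out.vbar = lo; out.resid = glo * mp.pen; out.clipped = 1; return out; }
  if (ghi <= 0.0) { out.vbar = hi; out.resid = ghi * mp.pen; out.clipped = 1; return out; }
  double g0 = afl + rest;   // g at v = 0
  double root;
  if (g0 > 0.0) {
    // shortening branch: g(v)*(1 - K v) is quadratic in v on [-1, 0]
    if (quad_root(-damp * mp.fvK, afl + damp - rest * mp.fvK, afl + rest,
                  -1.0, 0.0, root)) {
      out.vbar = root; out.resid = g(root) * mp.pen;
      if (std::fabs(out.resid) < 1e-8 * mp.fmax) return out;
    }
  } else {
    // lengthening branch: g(v)*(1 + c v) is quadratic in v on [0, 1]
    double c = 7.56 * mp.fvK;
    if (quad_root(damp * c, afl * mp.fvN * c + damp + rest * c, afl + rest,
                  0.0, 1.0, root)) {
      out.vbar = root; out.resid = g(root) * mp.pen;
      if (std::fabs(out.resid) < 1e-8 * mp.fmax) return out;
    }
  }
  double v = std::min(hi - 1e-9, std::max(lo + 1e-9, hint));
  double gv, dv;
  gdg(v, gv, dv);
  for (int it = 0; it < 60; ++it) {
    if (std::fabs(gv) < 1e-8 * mp.fmax) break;
    if (gv > 0.0) hi = v; else lo = v;
    double vn = (dv > 1e-12) ? v - gv / dv : 0.5 * (lo + hi);
    if (!(vn > lo && vn < hi)) vn = 0.5 * (lo + hi);
    v = vn;
    gdg(v, gv, dv);
  }
  out.vbar = v; out.resid = gv * mp.pen;
  return out;
}

// ------------------------------------------------------------- controller --

// dead-zone gate in [-1, 1] as a function of COM x in the platform frame
static double gate_factor(double x, double heel_x, double toe_x,
                          double x_heel, double x_toe, double z_heel, double z_toe) {
  double bh = heel_x + x_heel;      // heel-side dead-zone edge
  double bt = toe_x - x_toe;        // toe-side dead-zone edge
  double wh = z_heel * x_heel, wt = z_toe * x_toe;
  if (x < bh - wh) return -1.0;
  if (x < bh) return wh > 0.0 ? -(bh - x) / wh : -1.0;
  if (x <= bt) return 0.0;
  if (x <= bt + wt) return wt > 0.0 ? (x - bt) / wt : 1.0;
  return 1.0;
}

// Fixed-lag ring buffer: with delay d (>= 1) steps, reading at step s
// *before* pushing the step-s sample returns the sample pushed at step s - d,
// i.e. an exact lag of d*dt.  Reads before d pushes return the initial value.
struct Ring {
  std::vector<double> buf;
  int head = 0, dsteps = 0;
  void init(int d, double v0) {
    dsteps = d; buf.assign(std::max(d, 1), v0); head = (int)buf.size() - 1;
  }
  double read() const { return buf[(head + 1) % buf.size()]; }  // oldest
  void push(double v) { head = (head + 1) % (int)buf.size(); buf[head] = v; }
};

// ------------------------------------------------------------ R interface --

// [[Rcpp::export]]
List rs_forward_dynamics_cpp(List plant, NumericVector q, NumericVector qd,
                             NumericVector tau6, double platform_v, bool contact_on) {
  Plant p = plant_from_list(plant);
  DynScratch sc;
  double qdd[NQ], gy, gx, cf[8] = {0};
  dyn_qdd(p, sc, q.begin(), qd.begin(), tau6.begin(), platform_v, contact_on,
          qdd, &gy, &gx, cf);
  NumericMatrix cfm(4, 2);
  for (int i = 0; i < 4; ++i) { cfm(i, 0) = cf[2 * i]; cfm(i, 1) = cf[2 * i + 1]; }
  return List::create(_["qdd"] = NumericVector(qdd, qdd + NQ),
                      _["grf_y"] = gy, _["grf_x"] = gx,
                      _["contact_forces"] = cfm);
}

// [[Rcpp::export]]
List rs_points_cpp(List plant, NumericVector q) {
  Plant p = plant_from_list(plant);
  DynScratch sc;
  double qd0[NQ] = {0};
  Kin k; kin_compute(p, q.begin(), qd0, k);
  PointK pk;
  CVec chain[3];
  List out;
  auto store = [&](std::string nm, const CVec* ch, int n) {
    point_kin(k, q.begin(), qd0, ch, n, pk);
    out[nm] = NumericVector::create(pk.x, pk.y);
  };
  CVec trunkTop = {0, 0.0, p.L_t};
  store("chest", &trunkTop, 1);
  for (int leg = 0; leg < 2; ++leg) {
    std::string s = leg == 0 ? "_l" : "_r";
    int a0 = 1 + 3 * leg;
    CVec kn[1] = {{a0, 0.0, -p.L_th}};
    store("knee" + s, kn, 1);
    CVec an[2] = {{a0, 0.0, -p.L_th}, {a0 + 1, 0.0, -p.L_sh}};
    store("ankle" + s, an, 2);
    contact_chain(p, leg, true, chain);  store("heel" + s, chain, 3);
    contact_chain(p, leg, false, chain); store("toe" + s, chain, 3);
  }
  double cx, cy;
  com_position(p, sc, q.begin(), cx, cy);
  out["com"] = NumericVector::create(cx, cy);
  out["hip"] = NumericVector::create(q[0], q[1]);
  return out;
}

// [[Rcpp::export]]
NumericVector rs_com_cpp(List plant, NumericVector q) {
  Plant p = plant_from_list(plant);
  DynScratch sc;
  double cx, cy;
  com_position(p, sc, q.begin(), cx, cy);
  return NumericVector::create(cx, cy);
}

// [[Rcpp::export]]
double rs_energy_cpp(List plant, NumericVector q, NumericVector qd) {
  Plant p = plant_from_list(plant);
  DynScratch sc;
  if (!sc.init) { build_bodies(p, sc.B); sc.init = true; }
  Kin k; kin_compute(p, q.begin(), qd.begin(), k);
  PointK pk;
  double E = 0.0;
  for (int b = 0; b < 7; ++b) {
    point_kin(k, q.begin(), qd.begin(), sc.B[b].chain, sc.B[b].n, pk);
    double w = k.ad[sc.B[b].aidx];
    E += 0.5 * sc.B[b].m * (pk.vx * pk.vx + pk.vy * pk.vy)
       + 0.5 * sc.B[b].I * w * w
       + sc.B[b].m * p.g * pk.y;
  }
  return E;
}

// passive / PD-held simulation used for physics tests and settling
// [[Rcpp::export]]
List rs_passive_sim_cpp(List plant, NumericVector q0, NumericVector qd0,
                        double dt, int n_steps, bool contact_on,
                        NumericVector pd_kp, NumericVector pd_kd,
                        NumericVector q_ref, bool pd_on,
                        NumericVector platform_pos, int log_every) {
  Plant p = plant_from_list(plant);
  DynScratch sc;
  std::vector<double> q(q0.begin(), q0.end()), qd(qd0.begin(), qd0.end());
  int nlog = n_steps / log_every + 1;
  NumericMatrix qlog(nlog, NQ), qdlog(nlog, NQ);
  NumericVector elog(nlog), tlog(nlog), grflog(nlog);
  int li = 0;
  double qdd[NQ], tau6[6], gy = 0.0;
  bool use_plat = platform_pos.size() > 1;
  for (int s = 0; s <= n_steps; ++s) {
    if (s % log_every == 0 && li < nlog) {
      for (int i = 0; i < NQ; ++i) { qlog(li, i) = q[i]; qdlog(li, i) = qd[i]; }
      elog[li] = rs_energy_cpp(plant, NumericVector(q.begin(), q.end()),
                               NumericVector(qd.begin(), qd.end()));
      tlog[li] = s * dt;
      grflog[li] = gy;
      ++li;
    }
    if (s == n_steps) break;
    for (int j = 0; j < 6; ++j) tau6[j] = 0.0;
    if (pd_on) {
      for (int leg = 0; leg < 2; ++leg)
        for (int j = 0; j < 3; ++j) {
          int qi = 3 + 3 * leg + j;
          tau6[3 * leg + j] = pd_kp[j] * (q_ref[qi] - q[qi]) - pd_kd[j] * qd[qi];
        }
    }
    double pv = 0.0;
    if (use_plat) {
      int idx = std::min<int>(s, platform_pos.size() - 2);
      pv = (platform_pos[idx + 1] - platform_pos[idx]) / dt;
    }
    dyn_qdd(p, sc, q.data(), qd.data(), tau6, pv, contact_on, qdd, &gy);
    for (int i = 0; i < NQ; ++i) {
      if (!std::isfinite(qdd[i])) stop("NaN/Inf in derivatives at t=%f", s * dt);
      qd[i] += dt * qdd[i];
      q[i] += dt * qd[i];
    }
  }
  // final accelerations (diagnostic for equilibrium tests)
  for (int j = 0; j < 6; ++j) tau6[j] = 0.0;
  if (pd_on)
    for (int leg = 0; leg < 2; ++leg)
      for (int j = 0; j < 3; ++j) {
        int qi = 3 + 3 * leg + j;
        tau6[3 * leg + j] = pd_kp[j] * (q_ref[qi] - q[qi]) - pd_kd[j] * qd[qi];
      }
  dyn_qdd(p, sc, q.data(), qd.data(), tau6, 0.0, contact_on, qdd, &gy);
  return List::create(_["t"] = tlog, _["q"] = qlog, _["qd"] = qdlog,
                      _["energy"] = elog, _["grf_y"] = grflog,
                      _["final_qdd"] = NumericVector(qdd, qdd + NQ),
                      _["final_grf_y"] = gy);
}

// muscle-level hooks -------------------------------------------------------

// [[Rcpp::export]]
double rs_see_force_cpp(NumericMatrix mus, int i, double l_see) {
  MusPar mp = muspar_from_row(mus, i - 1);
  return see_force(mp, l_see);
}

// [[Rcpp::export]]
List rs_contraction_cpp(NumericMatrix mus, int i, double lce, double act, double lmtu) {
  MusPar mp = muspar_from_row(mus, i - 1);
  CERate cr = solve_vce(mp, lce, act, lmtu);
  double v = cr.vbar * mp.lopt * mp.vmax;
  double l_see = lmtu - mp.pen * lce;
  return List::create(_["dlce_dt"] = v, _["vbar"] = cr.vbar,
                      _["residual"] = cr.resid, _["clipped"] = cr.clipped,
                      _["f_see"] = see_force(mp, l_see),
                      _["f_l"] = fl_curve(mp, lce), _["f_pe"] = pe_force(mp, lce),
                      _["f_be"] = be_force(mp, lce));
}

// [[Rcpp::export]]
List rs_muscle_geometry_cpp(NumericMatrix mus, NumericVector joint_angles) {
  int n = mus.nrow();
  NumericVector lmtu(n);
  NumericMatrix arms(n, 3);
  for (int i = 0; i < n; ++i) {
    MusPar mp = muspar_from_row(mus, i);
    lmtu[i] = mtu_length(mp, joint_angles.begin());
    for (int j = 0; j < 3; ++j) arms(i, j) = moment_arm(mp, j, joint_angles[j]);
  }
  return List::create(_["lmtu"] = lmtu, _["moment_arms"] = arms);
}

// [[Rcpp::export]]
double rs_gate_cpp(double x_com, double heel_x, double toe_x,
                   double x_heel, double x_toe, double z_heel, double z_toe) {
  return gate_factor(x_com, heel_x, toe_x, x_heel, x_toe, z_heel, z_toe);
}

// [[Rcpp::export]]
NumericVector rs_delay_probe_cpp(NumericVector values, int dsteps, double init) {
  NumericVector out(values.size());
  if (dsteps == 0) return clone(values);
  Ring r; r.init(dsteps, init);
  for (int i = 0; i < values.size(); ++i) {
    out[i] = r.read();
    r.push(values[i]);
  }
  return out;
}

// ------------------------------------------------------------ episode -----

// [[Rcpp::export]]
List rs_run_episode_cpp(List plant, NumericMatrix mus, List ctrl, List cfg,
                        NumericVector platform_pos) {
  Plant p = plant_from_list(plant);
  DynScratch sc;
  const int nm = mus.nrow();          // muscles per leg (9)
  std::vector<MusPar> MP(nm);
  for (int i = 0; i < nm; ++i) MP[i] = muspar_from_row(mus, i);

  NumericVector u0 = ctrl["u0"], gf = ctrl["g_ffb"], gl = ctrl["g_lfb"],
                loff = ctrl["l_off"];
  double x_heel = ctrl["x_heel"], x_toe = ctrl["x_toe"],
         z_heel = ctrl["z_heel"], z_toe = ctrl["z_toe"];
  IntegerVector dsteps = ctrl["delay_steps"];
  int com_dsteps = ctrl["com_delay_steps"];

  double dt = cfg["dt"];
  double t_pd = cfg["t_pd"], t_quiet = cfg["t_quiet"], t_total = cfg["t_total"];
  double chest_fall = cfg["chest_fall"], horizon = cfg["horizon"];
  NumericVector pd_kp = cfg["pd_kp"], pd_kd = cfg["pd_kd"];
  NumericVector q0 = cfg["q0"];
  int log_every = cfg["log_every"];

  int n_steps = (int)std::llround(t_total / dt);
  int s_onset = (int)std::llround((t_pd + t_quiet) / dt);
  int s_pd_end = (int)std::llround(t_pd / dt);
  int s_T_end = s_onset + (int)std::llround(horizon / dt);

  std::vector<double> q(q0.begin(), q0.end()), qd(NQ, 0.0);
  // muscle state per leg (leg-major: leg*nm + i)
  std::vector<double> lce(2 * nm), act(2 * nm), fsee(2 * nm, 0.0);
  std::vector<Ring> bufF(2 * nm), bufL(2 * nm);
  Ring bufCom;
  // CE lengths start with the tendon at slack in the initial posture, so
  // muscle forces build up from zero during the joint-angle control phase
  {
    double th0[3] = {q0[3], q0[4], q0[5]};
    for (int leg = 0; leg < 2; ++leg)
      for (int i = 0; i < nm; ++i) {
        double l0 = (mtu_length(MP[i], th0) - MP[i].lslack) / MP[i].pen;
        l0 = std::min(1.6 * MP[i].lopt, std::max(0.5 * MP[i].lopt, l0));
        lce[leg * nm + i] = l0;
        double a0i = std::min(1.0, std::max(0.001, (double)u0[i]));
        act[leg * nm + i] = a0i;
        bufF[leg * nm + i].init(dsteps[i], 0.0);
        bufL[leg * nm + i].init(dsteps[i], l0 / MP[i].lopt);
      }
  }

  int nlog = n_steps / log_every + 2;
  NumericVector Lt(nlog), Ltrx(nlog), Ltry(nlog), Lpitch(nlog),
      Lhip(nlog), Lknee(nlog), Lankle(nlog),
      Lmhip(nlog), Lmknee(nlog), Lmankle(nlog),
      Lcomx(nlog), Lcomy(nlog), Lchest(nlog), Lanklex(nlog),
      Lgrf(nlog), Lplat(nlog), Lsuma2(nlog), Lgate(nlog);
  int li = 0;

  double qdd[NQ], tau6[6];
  double effort_acc = 0.0;
  double excur_acc = 0.0; long excur_n = 0;
  double ankle_ref = NA_REAL;
  bool fell = false;
  double survived = t_total;
  int clip_count = 0;
  double chest_T = NA_REAL;
  std::vector<double> vhint(2 * nm, 0.0);

  sc_init(p, sc);
  CVec chain[3];
  PointK pk;
  PointK bodypk[7];
  Kin k;

  for (int s = 0; s <= n_steps; ++s) {
    double t = s * dt;
    int pidx = std::min<int>(s, platform_pos.size() - 1);
    double px = platform_pos[pidx];
    double pv = (s + 1 < platform_pos.size())
                  ? (platform_pos[pidx + 1] - platform_pos[pidx]) / dt : 0.0;

    kin_compute(p, q.data(), qd.data(), k);
    // one kinematics pass per step: body COM kinematics feed both the COM
    // gate and the mass-matrix assembly below
    double cx = 0.0, cy = 0.0, mtot = 0.0;
    for (int b = 0; b < 7; ++b) {
      point_kin(k, q.data(), qd.data(), sc.B[b].chain, sc.B[b].n, bodypk[b]);
      cx += sc.B[b].m * bodypk[b].x; cy += sc.B[b].m * bodypk[b].y;
      mtot += sc.B[b].m;
    }
    cx /= mtot; cy /= mtot;
    // contact reference points (average over legs)
    double heelx = 0.0, toex = 0.0, anklex = 0.0;
    for (int leg = 0; leg < 2; ++leg) {
      contact_chain(p, leg, true, chain);
      point_kin(k, q.data(), qd.data(), chain, 3, pk); heelx += 0.5 * pk.x;
      contact_chain(p, leg, false, chain);
      point_kin(k, q.data(), qd.data(), chain, 3, pk); toex += 0.5 * pk.x;
      CVec an[2] = {{1 + 3 * leg, 0.0, -p.L_th}, {2 + 3 * leg, 0.0, -p.L_sh}};
      point_kin(k, q.data(), qd.data(), an, 2, pk); anklex += 0.5 * pk.x;
    }
    CVec trunkTop = {0, 0.0, p.L_t};
    point_kin(k, q.data(), qd.data(), &trunkTop, 1, pk);
    double chest_y = pk.y;

    if (s == s_onset) ankle_ref = anklex - px;
    double ankle_rel = (s >= s_onset) ? (anklex - px) - ankle_ref : 0.0;

    // COM gate (optionally delayed COM signal)
    if (s == 0) bufCom.init(com_dsteps, cx);
    double com_x_eff = cx;
    if (com_dsteps > 0) { com_x_eff = bufCom.read(); bufCom.push(cx); }
    double gatef = gate_factor(com_x_eff, heelx, toex, x_heel, x_toe, z_heel, z_toe);

    // controller + muscles
    double joint_m[6] = {0, 0, 0, 0, 0, 0};
    double suma2 = 0.0;
    bool fb_on = s >= s_pd_end;   // reflex feedback once joint-angle phase ends
    for (int leg = 0; leg < 2; ++leg) {
      double th[3] = {q[3 + 3 * leg], q[4 + 3 * leg], q[5 + 3 * leg]};
      for (int i = 0; i < nm; ++i) {
        int mi = leg * nm + i;
        const MusPar& mp = MP[i];
        // stimulation from delayed, normalized sensors
        double u = u0[i];
        if (fb_on) {
          double fhat = bufF[mi].read();
          double lhat = bufL[mi].read();
          u += gatef * gf[i] * fhat;
          if (lhat > loff[i]) u += gatef * gl[i] * (lhat - loff[i]);
        }
        u = std::min(1.0, std::max(0.001, u));
        // activation dynamics
        double tau_a = (u > act[mi]) ? mp.tact : mp.tdeact;
        act[mi] += dt * (u - act[mi]) / tau_a;
        act[mi] = std::min(1.0, std::max(0.0, act[mi]));
        // contraction dynamics (warm-started from the previous step's rate)
        double lmtu = mtu_length(mp, th);
        CERate cr = solve_vce(mp, lce[mi], act[mi], lmtu, vhint[mi]);
        vhint[mi] = cr.vbar;
        if (cr.clipped) ++clip_count;
        lce[mi] += dt * cr.vbar * mp.lopt * mp.vmax;
        if (lce[mi] < 0.3 * mp.lopt) lce[mi] = 0.3 * mp.lopt;
        double lsee = lmtu - mp.pen * lce[mi];
        fsee[mi] = see_force(mp, lsee);
        // moments
        for (int j = 0; j < 3; ++j) {
          double ma = moment_arm(mp, j, th[j]);
          if (ma != 0.0) joint_m[3 * leg + j] += ma * fsee[mi];
        }
        // push sensors
        bufF[mi].push(fsee[mi] / mp.fmax);
        bufL[mi].push(lce[mi] / mp.lopt);
        suma2 += act[mi] * act[mi];
      }
    }

    // effort and excursion accumulation over [onset, onset + horizon]
    if (s >= s_onset && s < s_T_end) {
      effort_acc += suma2 * dt;
      excur_acc += std::fabs(ankle_rel); ++excur_n;
    }
    if (s == s_T_end) chest_T = chest_y;

    // logging
    if (s % log_every == 0 && li < nlog) {
      Lt[li] = t; Ltrx[li] = q[0]; Ltry[li] = q[1];
      Lpitch[li] = -q[2];
      Lhip[li] = 0.5 * (q[3] + q[6]); Lknee[li] = 0.5 * (q[4] + q[7]);
      Lankle[li] = 0.5 * (q[5] + q[8]);
      Lmhip[li] = 0.5 * (joint_m[0] + joint_m[3]);
      Lmknee[li] = 0.5 * (joint_m[1] + joint_m[4]);
      Lmankle[li] = 0.5 * (joint_m[2] + joint_m[5]);
      Lcomx[li] = cx; Lcomy[li] = cy; Lchest[li] = chest_y;
      Lanklex[li] = ankle_rel; Lplat[li] = px; Lsuma2[li] = suma2;
      Lgate[li] = gatef;
      ++li;
    }

    if (chest_y < chest_fall) { fell = true; survived = t; break; }
    if (s == n_steps) break;

    // plant step
    for (int j = 0; j < 6; ++j) tau6[j] = joint_m[j];
    if (s < s_pd_end)
      for (int leg = 0; leg < 2; ++leg)
        for (int j = 0; j < 3; ++j) {
          int qi = 3 + 3 * leg + j;
          tau6[3 * leg + j] += pd_kp[j] * (q0[qi] - q[qi]) - pd_kd[j] * qd[qi];
        }
    double gy;
    dyn_qdd_pk(p, sc, k, q.data(), qd.data(), bodypk, tau6, pv, true, qdd, &gy);
    if (li > 0) Lgrf[li - 1] = gy;
    for (int i = 0; i < NQ; ++i) {
      if (!std::isfinite(qdd[i])) {
        fell = true; survived = t;
        break;
      }
      qd[i] += dt * qdd[i];
      q[i] += dt * qd[i];
    }
    if (fell) break;
  }

  double T = horizon;
  double effort = effort_acc / T;
  double excursion = excur_n > 0 ? excur_acc / excur_n : 0.0;

  DataFrame traj = DataFrame::create(
      _["time"] = head(Lt, li), _["trunk_x"] = head(Ltrx, li),
      _["trunk_y"] = head(Ltry, li), _["trunk_pitch"] = head(Lpitch, li),
      _["hip"] = head(Lhip, li), _["knee"] = head(Lknee, li),
      _["ankle"] = head(Lankle, li),
      _["hip_moment"] = head(Lmhip, li), _["knee_moment"] = head(Lmknee, li),
      _["ankle_moment"] = head(Lmankle, li),
      _["com_x"] = head(Lcomx, li), _["com_y"] = head(Lcomy, li),
      _["chest_y"] = head(Lchest, li), _["ankle_x"] = head(Lanklex, li),
      _["grf_y"] = head(Lgrf, li), _["platform_x"] = head(Lplat, li),
      _["sum_a2"] = head(Lsuma2, li), _["gate"] = head(Lgate, li));

  return List::create(_["survived"] = survived, _["fell"] = fell,
                      _["effort"] = effort, _["excursion"] = excursion,
                      _["chest_T"] = chest_T, _["trajectory"] = traj,
                      _["clip_count"] = clip_count);
}
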