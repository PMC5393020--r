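// Compiled residual / tangent kernels for the multibody solver.
//
// These mirror the reference element implementations in R/elements.R
// (which remain the documented, testable definitions); the kernels exist
// because equilibrium solving evaluates every element thousands of times
// per simulation. The test suite cross-checks both paths on random
// states.
//
// Conventions: state is passed as x (3 x n body origins) and Rmat
// (9 x n, column-major 3x3 rotation per body column); packed element
// tables store one element per COLUMN so that &mat(0, e) is contiguous.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// R (3x3 column-major) times v
static inline void rotate(const double* R, const double* v, double* out) {
  out[0] = R[0] * v[0] + R[3] * v[1] + R[6] * v[2];
  out[1] = R[1] * v[0] + R[4] * v[1] + R[7] * v[2];
  out[2] = R[2] * v[0] + R[5] * v[1] + R[8] * v[2];
}

// R^T times v
static inline void rotate_t(const double* R, const double* v, double* out) {
  out[0] = R[0] * v[0] + R[1] * v[1] + R[2] * v[2];
  out[1] = R[3] * v[0] + R[4] * v[1] + R[5] * v[2];
  out[2] = R[6] * v[0] + R[7] * v[1] + R[8] * v[2];
}

// C = A * B (3x3 column-major)
static inline void matmul3(const double* A, const double* B, double* C) {
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      C[r + 3 * c] = A[r] * B[3 * c] + A[r + 3] * B[1 + 3 * c] +
        A[r + 6] * B[2 + 3 * c];
}

// C = A^T * B
static inline void matTmul3(const double* A, const double* B, double* C) {
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      C[r + 3 * c] = A[3 * r] * B[3 * c] + A[1 + 3 * r] * B[1 + 3 * c] +
        A[2 + 3 * r] * B[2 + 3 * c];
}

// C = A * B^T
static inline void matmulT3(const double* A, const double* B, double* C) {
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      C[r + 3 * c] = A[r] * B[c] + A[r + 3] * B[c + 3] + A[r + 6] * B[c + 6];
}

// rotation matrix -> rotation vector, matching matrix_to_rotvec() in R
static void mat2rotvec(const double* R, double* v) {
  double tr = R[0] + R[4] + R[8];
  double c = (tr - 1.0) / 2.0;
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  double th = std::acos(c);
  double w[3] = { R[5] - R[7], R[6] - R[2], R[1] - R[3] };
  if (th < 1e-8) {
    v[0] = 0.5 * w[0]; v[1] = 0.5 * w[1]; v[2] = 0.5 * w[2];
    return;
  }
  if (th > M_PI - 1e-6) {
    double A[9];
    for (int k = 0; k < 9; ++k) A[k] = R[k] / 2.0;
    A[0] += 0.5; A[4] += 0.5; A[8] += 0.5;
    double d[3] = { A[0] > 0 ? std::sqrt(A[0]) : 0.0,
                    A[4] > 0 ? std::sqrt(A[4]) : 0.0,
                    A[8] > 0 ? std::sqrt(A[8]) : 0.0 };
    int i = 0;
    if (d[1] > d[i]) i = 1;
    if (d[2] > d[i]) i = 2;
    double a0 = A[3 * i] / d[i], a1 = A[1 + 3 * i] / d[i],
      a2 = A[2 + 3 * i] / d[i];
    double nrm = std::sqrt(a0 * a0 + a1 * a1 + a2 * a2);
    v[0] = th * a0 / nrm; v[1] = th * a1 / nrm; v[2] = th * a2 / nrm;
    return;
  }
  double s = th / (2.0 * std::sin(th));
  v[0] = s * w[0]; v[1] = s * w[1]; v[2] = s * w[2];
}

// rotation vector -> rotation matrix (Rodrigues)
static void rotvec2mat(const double* v, double* R) {
  double th = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  if (th < 1e-12) {
    R[0] = 1; R[1] = v[2]; R[2] = -v[1];
    R[3] = -v[2]; R[4] = 1; R[5] = v[0];
    R[6] = v[1]; R[7] = -v[0]; R[8] = 1;
    return;
  }
  double kx = v[0] / th, ky = v[1] / th, kz = v[2] / th;
  double ct = std::cos(th), st = std::sin(th), vt = 1.0 - ct;
  R[0] = ct + kx * kx * vt;
  R[1] = kz * st + kx * ky * vt;
  R[2] = -ky * st + kx * kz * vt;
  R[3] = -kz * st + kx * ky * vt;
  R[4] = ct + ky * ky * vt;
  R[5] = kx * st + ky * kz * vt;
  R[6] = ky * st + kx * kz * vt;
  R[7] = -kx * st + ky * kz * vt;
  R[8] = ct + kz * kz * vt;
}

// C1-smoothed tension law (matches .smooth_tension in R, eps = 0.02):
// exactly zero at and below the rest length, exactly k*e beyond 2*eps
static inline void smooth_tension(double k, double e, double* f, double* df) {
  const double eps = 0.02;
  if (e <= 0.0) { *f = 0.0; *df = 0.0; return; }
  if (e >= 2.0 * eps) { *f = k * e; *df = k; return; }
  *f = k * e * e / eps - k * e * e * e / (4.0 * eps * eps);
  *df = 2.0 * k * e / eps - 3.0 * k * e * e / (4.0 * eps * eps);
}

struct RodlineGeom {
  bool active;
  double ci[3], cj[3], w[3], L, L0;
};

// closest points between the (clamped) screw-axis segment and the rod
// axis line; matches .rodline_geom in R
static RodlineGeom rodline_geom(const double* xi, const double* Ri,
                                const double* xj, const double* Rj,
                                const double* a_i, const double* a_j,
                                const double* dir_i, double L0s, double L0e,
                                double s_max, double t_max, double ramp_s) {
  RodlineGeom g;
  double pi_[3], pj_[3], u[3], v[3], tmp[3];
  rotate(Ri, a_i, tmp);
  for (int k = 0; k < 3; ++k) pi_[k] = xi[k] + tmp[k];
  rotate(Rj, a_j, tmp);
  for (int k = 0; k < 3; ++k) pj_[k] = xj[k] + tmp[k];
  rotate(Ri, dir_i, u);
  double az[3] = { 0.0, 0.0, 1.0 };
  rotate(Rj, az, v);
  double r[3] = { pj_[0] - pi_[0], pj_[1] - pi_[1], pj_[2] - pi_[2] };
  double b = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
  double den = 1.0 - b * b;
  double ru = r[0] * u[0] + r[1] * u[1] + r[2] * u[2];
  double rv = r[0] * v[0] + r[1] * v[1] + r[2] * v[2];
  double s_ = (std::fabs(den) < 1e-8) ? ru : (ru - b * rv) / den;
  if (s_ < 0.0) s_ = 0.0;
  if (s_ > s_max) s_ = s_max;
  for (int k = 0; k < 3; ++k) g.ci[k] = pi_[k] + s_ * u[k];
  double t_ = (g.ci[0] - pj_[0]) * v[0] + (g.ci[1] - pj_[1]) * v[1] +
    (g.ci[2] - pj_[2]) * v[2];
  if (t_ < -t_max) t_ = -t_max;
  if (t_ > t_max) t_ = t_max;
  for (int k = 0; k < 3; ++k) {
    g.cj[k] = pj_[k] + t_ * v[k];
    g.w[k] = g.cj[k] - g.ci[k];
  }
  g.L = std::sqrt(g.w[0] * g.w[0] + g.w[1] * g.w[1] + g.w[2] * g.w[2]);
  g.L0 = L0s + ramp_s * (L0e - L0s);
  g.active = !(g.L <= g.L0 || g.L < 1e-9);
  return g;
}

// [[Rcpp::export(name = ".residual_cpp")]]
NumericMatrix residual_cpp(NumericMatrix x, NumericMatrix Rmat, List packed,
                           double ramp_s) {
  int n = x.ncol();
  NumericMatrix Fg(n, 6);

  IntegerMatrix c_idx = packed["c_idx"];      // 2 x m
  NumericMatrix c_ai = packed["c_ai"], c_aj = packed["c_aj"],
    c_par = packed["c_par"];                  // 3 x m, 3 x m, 4 x m
  for (int e = 0; e < c_idx.ncol(); ++e) {
    int bi = c_idx(0, e) - 1, bj = c_idx(1, e) - 1;
    double pi_[3], pj_[3], tmp[3];
    rotate(&Rmat(0, bi), &c_ai(0, e), tmp);
    for (int k = 0; k < 3; ++k) pi_[k] = x(k, bi) + tmp[k];
    rotate(&Rmat(0, bj), &c_aj(0, e), tmp);
    for (int k = 0; k < 3; ++k) pj_[k] = x(k, bj) + tmp[k];
    double d[3] = { pj_[0] - pi_[0], pj_[1] - pi_[1], pj_[2] - pi_[2] };
    double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (L < 1e-9) continue;
    double L0 = c_par(1, e);
    if (c_par(3, e) > 0.5) L0 += ramp_s * (c_par(2, e) - c_par(1, e));
    double f, df;
    smooth_tension(c_par(0, e), L - L0, &f, &df);
    if (f == 0.0) continue;
    double fv[3] = { f * d[0] / L, f * d[1] / L, f * d[2] / L };
    double ci[3] = { pi_[0] - x(0, bi), pi_[1] - x(1, bi), pi_[2] - x(2, bi) };
    double cj[3] = { pj_[0] - x(0, bj), pj_[1] - x(1, bj), pj_[2] - x(2, bj) };
    double ti[3], tj[3];
    cross3(ci, fv, ti);
    cross3(cj, fv, tj);
    for (int k = 0; k < 3; ++k) {
      Fg(bi, k) += fv[k];     Fg(bi, 3 + k) += ti[k];
      Fg(bj, k) -= fv[k];     Fg(bj, 3 + k) -= tj[k];
    }
  }

  IntegerMatrix r_idx = packed["r_idx"];
  NumericMatrix r_ai = packed["r_ai"], r_aj = packed["r_aj"],
    r_dir = packed["r_dir"], r_par = packed["r_par"];   // 5 x m
  for (int e = 0; e < r_idx.ncol(); ++e) {
    int bi = r_idx(0, e) - 1, bj = r_idx(1, e) - 1;
    RodlineGeom g = rodline_geom(&x(0, bi), &Rmat(0, bi), &x(0, bj),
                                 &Rmat(0, bj), &r_ai(0, e), &r_aj(0, e),
                                 &r_dir(0, e), r_par(1, e), r_par(2, e),
                                 r_par(3, e), r_par(4, e), ramp_s);
    if (!g.active) continue;
    double f, df;
    smooth_tension(r_par(0, e), g.L - g.L0, &f, &df);
    if (f == 0.0) continue;
    double fv[3] = { f * g.w[0] / g.L, f * g.w[1] / g.L, f * g.w[2] / g.L };
    double ci[3] = { g.ci[0] - x(0, bi), g.ci[1] - x(1, bi),
                     g.ci[2] - x(2, bi) };
    double cj[3] = { g.cj[0] - x(0, bj), g.cj[1] - x(1, bj),
                     g.cj[2] - x(2, bj) };
    double ti[3], tj[3];
    cross3(ci, fv, ti);
    cross3(cj, fv, tj);
    for (int k = 0; k < 3; ++k) {
      Fg(bi, k) += fv[k];     Fg(bi, 3 + k) += ti[k];
      Fg(bj, k) -= fv[k];     Fg(bj, 3 + k) -= tj[k];
    }
  }

  IntegerMatrix s_idx = packed["s_idx"];
  NumericMatrix s_ai = packed["s_ai"], s_aj = packed["s_aj"],
    s_Bi = packed["s_Bi"], s_Bj = packed["s_Bj"], s_dt0 = packed["s_dt0"],
    s_D0 = packed["s_D0"], s_K = packed["s_K"], s_bil = packed["s_bil"],
    s_ramp = packed["s_ramp"];
  for (int e = 0; e < s_idx.ncol(); ++e) {
    int bi = s_idx(0, e) - 1, bj = s_idx(1, e) - 1;
    double pi_[3], pj_[3], tmp[3];
    rotate(&Rmat(0, bi), &s_ai(0, e), tmp);
    for (int k = 0; k < 3; ++k) pi_[k] = x(k, bi) + tmp[k];
    rotate(&Rmat(0, bj), &s_aj(0, e), tmp);
    for (int k = 0; k < 3; ++k) pj_[k] = x(k, bj) + tmp[k];
    double Ai[9], Aj[9];
    matmul3(&Rmat(0, bi), &s_Bi(0, e), Ai);
    matmul3(&Rmat(0, bj), &s_Bj(0, e), Aj);
    double dvec[3] = { pj_[0] - pi_[0], pj_[1] - pi_[1], pj_[2] - pi_[2] };
    double dt[3];
    rotate_t(Ai, dvec, dt);
    for (int k = 0; k < 3; ++k) dt[k] -= s_dt0(k, e);
    double D0[9];
    if (s_ramp(3, e) > 0.5) {
      double rv[3] = { ramp_s * s_ramp(0, e), ramp_s * s_ramp(1, e),
                       ramp_s * s_ramp(2, e) };
      double Rr[9];
      rotvec2mat(rv, Rr);
      matmul3(&s_D0(0, e), Rr, D0);
    } else {
      for (int k = 0; k < 9; ++k) D0[k] = s_D0(k, e);
    }
    double AtA[9], Dd[9];
    matTmul3(Ai, Aj, AtA);
    matmulT3(AtA, D0, Dd);
    double dr[3];
    mat2rotvec(Dd, dr);
    double k44 = s_K(3 + 6 * 3, e);
    if (s_bil(1, e) > 0.0 && s_bil(1, e) != 1.0) {
      double wgt = std::tanh(dr[0] * s_bil(0, e) / 0.002);
      k44 = k44 * std::pow(s_bil(1, e), wgt);
    }
    double dvec6[6] = { dt[0], dt[1], dt[2], dr[0], dr[1], dr[2] };
    double w6[6];
    for (int r = 0; r < 6; ++r) {
      double acc = 0.0;
      for (int c = 0; c < 6; ++c) {
        double kk = s_K(r + 6 * c, e);
        if (r == 3 && c == 3) kk = k44;
        acc += kk * dvec6[c];
      }
      w6[r] = acc;
    }
    double f[3], tau[3];
    rotate(Ai, w6, f);
    rotate(Ai, w6 + 3, tau);
    double mid[3] = { (pi_[0] + pj_[0]) / 2.0, (pi_[1] + pj_[1]) / 2.0,
                      (pi_[2] + pj_[2]) / 2.0 };
    double ri[3] = { mid[0] - x(0, bi), mid[1] - x(1, bi), mid[2] - x(2, bi) };
    double rj[3] = { mid[0] - x(0, bj), mid[1] - x(1, bj), mid[2] - x(2, bj) };
    double cri[3], crj[3];
    cross3(ri, f, cri);
    cross3(rj, f, crj);
    for (int k = 0; k < 3; ++k) {
      Fg(bi, k) += f[k];      Fg(bi, 3 + k) += tau[k] + cri[k];
      Fg(bj, k) -= f[k];      Fg(bj, 3 + k) -= tau[k] + crj[k];
    }
  }

  IntegerVector g_idx = packed["g_idx"];
  NumericMatrix g_par = packed["g_par"], g_X0 = packed["g_X0"],
    g_R0 = packed["g_R0"];
  for (int e = 0; e < g_idx.size(); ++e) {
    int b = g_idx[e] - 1;
    double RRt[9];
    matmulT3(&Rmat(0, b), &g_R0(0, e), RRt);
    double rv[3];
    mat2rotvec(RRt, rv);
    for (int k = 0; k < 3; ++k) {
      Fg(b, k) += -g_par(0, e) * (x(k, b) - g_X0(k, e));
      Fg(b, 3 + k) += -g_par(1, e) * rv[k];
    }
  }

  return Fg;
}

// accumulate t(M) %*% Kt %*% M for M = [-I, skew(ci), I, -skew(cj)]
static void add_trans_tangent(NumericMatrix& J, int bi, int bj,
                              const double* Kt, const double* ci,
                              const double* cj) {
  double M[3][12] = {{0}};
  for (int r = 0; r < 3; ++r) { M[r][r] = -1.0; M[r][6 + r] = 1.0; }
  M[0][4] = -ci[2]; M[0][5] = ci[1];
  M[1][3] = ci[2];  M[1][5] = -ci[0];
  M[2][3] = -ci[1]; M[2][4] = ci[0];
  M[0][10] = cj[2];  M[0][11] = -cj[1];
  M[1][9] = -cj[2];  M[1][11] = cj[0];
  M[2][9] = cj[1];   M[2][10] = -cj[0];
  double KM[3][12];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 12; ++c)
      KM[r][c] = Kt[r] * M[0][c] + Kt[r + 3] * M[1][c] + Kt[r + 6] * M[2][c];
  double Kel[12][12];
  for (int r = 0; r < 12; ++r)
    for (int c = 0; c < 12; ++c)
      Kel[r][c] = M[0][r] * KM[0][c] + M[1][r] * KM[1][c] + M[2][r] * KM[2][c];
  int oi = 6 * bi, oj = 6 * bj;
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 6; ++c) {
      J(oi + r, oi + c) += Kel[r][c];
      J(oi + r, oj + c) += Kel[r][6 + c];
      J(oj + r, oi + c) += Kel[6 + r][c];
      J(oj + r, oj + c) += Kel[6 + r][6 + c];
    }
}

// [[Rcpp::export(name = ".tangent_cpp")]]
NumericMatrix tangent_cpp(NumericMatrix x, NumericMatrix Rmat, List packed,
                          double ramp_s) {
  int n = x.ncol();
  NumericMatrix J(6 * n, 6 * n);

  IntegerMatrix c_idx = packed["c_idx"];
  NumericMatrix c_ai = packed["c_ai"], c_aj = packed["c_aj"],
    c_par = packed["c_par"];
  for (int e = 0; e < c_idx.ncol(); ++e) {
    int bi = c_idx(0, e) - 1, bj = c_idx(1, e) - 1;
    double pi_[3], pj_[3], tmp[3];
    rotate(&Rmat(0, bi), &c_ai(0, e), tmp);
    for (int k = 0; k < 3; ++k) pi_[k] = x(k, bi) + tmp[k];
    rotate(&Rmat(0, bj), &c_aj(0, e), tmp);
    for (int k = 0; k < 3; ++k) pj_[k] = x(k, bj) + tmp[k];
    double d[3] = { pj_[0] - pi_[0], pj_[1] - pi_[1], pj_[2] - pi_[2] };
    double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (L < 1e-9) continue;
    double L0 = c_par(1, e);
    if (c_par(3, e) > 0.5) L0 += ramp_s * (c_par(2, e) - c_par(1, e));
    double f, df;
    smooth_tension(c_par(0, e), L - L0, &f, &df);
    if (f == 0.0 && df == 0.0) continue;
    double u[3] = { d[0] / L, d[1] / L, d[2] / L };
    double Kt[9];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) {
        double uu = u[r] * u[c];
        Kt[r + 3 * c] = df * uu + (f / L) * ((r == c ? 1.0 : 0.0) - uu);
      }
    double ci[3] = { pi_[0] - x(0, bi), pi_[1] - x(1, bi), pi_[2] - x(2, bi) };
    double cj[3] = { pj_[0] - x(0, bj), pj_[1] - x(1, bj), pj_[2] - x(2, bj) };
    add_trans_tangent(J, bi, bj, Kt, ci, cj);
  }

  IntegerMatrix r_idx = packed["r_idx"];
  NumericMatrix r_ai = packed["r_ai"], r_aj = packed["r_aj"],
    r_dir = packed["r_dir"], r_par = packed["r_par"];
  for (int e = 0; e < r_idx.ncol(); ++e) {
    int bi = r_idx(0, e) - 1, bj = r_idx(1, e) - 1;
    RodlineGeom g = rodline_geom(&x(0, bi), &Rmat(0, bi), &x(0, bj),
                                 &Rmat(0, bj), &r_ai(0, e), &r_aj(0, e),
                                 &r_dir(0, e), r_par(1, e), r_par(2, e),
                                 r_par(3, e), r_par(4, e), ramp_s);
    if (!g.active) continue;
    double f, df;
    smooth_tension(r_par(0, e), g.L - g.L0, &f, &df);
    if (f == 0.0 && df == 0.0) continue;
    double u[3] = { g.w[0] / g.L, g.w[1] / g.L, g.w[2] / g.L };
    double Kt[9];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c)
        Kt[r + 3 * c] = df * u[r] * u[c];   // material term only (PSD)
    double ci[3] = { g.ci[0] - x(0, bi), g.ci[1] - x(1, bi),
                     g.ci[2] - x(2, bi) };
    double cj[3] = { g.cj[0] - x(0, bj), g.cj[1] - x(1, bj),
                     g.cj[2] - x(2, bj) };
    add_trans_tangent(J, bi, bj, Kt, ci, cj);
  }

  IntegerMatrix s_idx = packed["s_idx"];
  NumericMatrix s_ai = packed["s_ai"], s_aj = packed["s_aj"],
    s_Bi = packed["s_Bi"], s_Bj = packed["s_Bj"], s_D0 = packed["s_D0"],
    s_K = packed["s_K"], s_bil = packed["s_bil"], s_ramp = packed["s_ramp"];
  for (int e = 0; e < s_idx.ncol(); ++e) {
    int bi = s_idx(0, e) - 1, bj = s_idx(1, e) - 1;
    double pi_[3], pj_[3], tmp[3];
    rotate(&Rmat(0, bi), &s_ai(0, e), tmp);
    for (int k = 0; k < 3; ++k) pi_[k] = x(k, bi) + tmp[k];
    rotate(&Rmat(0, bj), &s_aj(0, e), tmp);
    for (int k = 0; k < 3; ++k) pj_[k] = x(k, bj) + tmp[k];
    double Ai[9];
    matmul3(&Rmat(0, bi), &s_Bi(0, e), Ai);
    double k44 = s_K(3 + 6 * 3, e);
    if (s_bil(1, e) > 0.0 && s_bil(1, e) != 1.0) {
      double Aj[9], AtA[9], Dd[9], D0[9];
      matmul3(&Rmat(0, bj), &s_Bj(0, e), Aj);
      if (s_ramp(3, e) > 0.5) {
        double rv[3] = { ramp_s * s_ramp(0, e), ramp_s * s_ramp(1, e),
                         ramp_s * s_ramp(2, e) };
        double Rr[9];
        rotvec2mat(rv, Rr);
        matmul3(&s_D0(0, e), Rr, D0);
      } else {
        for (int k = 0; k < 9; ++k) D0[k] = s_D0(k, e);
      }
      matTmul3(Ai, Aj, AtA);
      matmulT3(AtA, D0, Dd);
      double dr[3];
      mat2rotvec(Dd, dr);
      double wgt = std::tanh(dr[0] * s_bil(0, e) / 0.002);
      k44 = k44 * std::pow(s_bil(1, e), wgt);
    }
    double At[9];   // Ai^T, column-major
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) At[r + 3 * c] = Ai[c + 3 * r];
    double arm_i[3] = { pj_[0] - x(0, bi), pj_[1] - x(1, bi),
                        pj_[2] - x(2, bi) };
    double cj[3] = { pj_[0] - x(0, bj), pj_[1] - x(1, bj),
                     pj_[2] - x(2, bj) };
    double Si[9] = { 0, arm_i[2], -arm_i[1],
                     -arm_i[2], 0, arm_i[0],
                     arm_i[1], -arm_i[0], 0 };
    double Sj[9] = { 0, cj[2], -cj[1],
                     -cj[2], 0, cj[0],
                     cj[1], -cj[0], 0 };
    double ASi[9], ASj[9];
    matmul3(At, Si, ASi);
    matmul3(At, Sj, ASj);
    double B[6][12] = {{0}};
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) {
        double a = At[r + 3 * c];
        B[r][c] = -a;         B[r][6 + c] = a;
        B[3 + r][3 + c] = -a; B[3 + r][9 + c] = a;
        B[r][3 + c] = ASi[r + 3 * c];
        B[r][9 + c] = -ASj[r + 3 * c];
      }
    double KB[6][12];
    for (int r = 0; r < 6; ++r)
      for (int c = 0; c < 12; ++c) {
        double acc = 0.0;
        for (int q = 0; q < 6; ++q) {
          double kk = s_K(r + 6 * q, e);
          if (r == 3 && q == 3) kk = k44;
          acc += kk * B[q][c];
        }
        KB[r][c] = acc;
      }
    double Kel[12][12];
    for (int r = 0; r < 12; ++r)
      for (int c = 0; c < 12; ++c) {
        double acc = 0.0;
        for (int q = 0; q < 6; ++q) acc += B[q][r] * KB[q][c];
        Kel[r][c] = acc;
      }
    int oi = 6 * bi, oj = 6 * bj;
    for (int r = 0; r < 6; ++r)
      for (int c = 0; c < 6; ++c) {
        J(oi + r, oi + c) += Kel[r][c];
        J(oi + r, oj + c) += Kel[r][6 + c];
        J(oj + r, oi + c) += Kel[6 + r][c];
        J(oj + r, oj + c) += Kel[6 + r][6 + c];
      }
  }

  IntegerVector g_idx = packed["g_idx"];
  NumericMatrix g_par = packed["g_par"];
  for (int e = 0; e < g_idx.size(); ++e) {
    int b = g_idx[e] - 1;
    int o = 6 * b;
    for (int k = 0; k < 3; ++k) {
      J(o + k, o + k) += g_par(0, e);
      J(o + 3 + k, o + 3 + k) += g_par(1, e);
    }
  }

  return J;
}
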