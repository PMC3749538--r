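// Total potential energy and analytic gradient of the spine model.
// Mirrors the reference R implementation (kept as a cross-check oracle in
// the test suite); all conventions are identical: left-incremental
// rotation vectors, torques mapped through the transposed left Jacobian.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

typedef double mat3[9];   // column-major 3x3

static inline void matvec(const double* M, const double* v, double* out) {
  out[0] = M[0] * v[0] + M[3] * v[1] + M[6] * v[2];
  out[1] = M[1] * v[0] + M[4] * v[1] + M[7] * v[2];
  out[2] = M[2] * v[0] + M[5] * v[1] + M[8] * v[2];
}
static inline void matTvec(const double* M, const double* v, double* out) {
  out[0] = M[0] * v[0] + M[1] * v[1] + M[2] * v[2];
  out[1] = M[3] * v[0] + M[4] * v[1] + M[5] * v[2];
  out[2] = M[6] * v[0] + M[7] * v[1] + M[8] * v[2];
}
static inline void matmul(const double* A, const double* B, double* C) {
  for (int j = 0; j < 3; ++j) matvec(A, B + 3 * j, C + 3 * j);
}
static inline void matTmul(const double* A, const double* B, double* C) {
  for (int j = 0; j < 3; ++j) matTvec(A, B + 3 * j, C + 3 * j);
}
// C = A * B^T
static inline void matmulT(const double* A, const double* B, double* C) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += A[i + 3 * k] * B[j + 3 * k];
      C[i + 3 * j] = s;
    }
}
static inline void cross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static void rot_exp(const double* q, double* R) {
  double th2 = dot3(q, q);
  double S[9] = {0, q[2], -q[1], -q[2], 0, q[0], q[1], -q[0], 0};
  double S2[9];
  matmul(S, S, S2);
  double a, b;
  if (th2 < 1e-16) { a = 1.0; b = 0.5; }
  else {
    double th = std::sqrt(th2);
    a = std::sin(th) / th;
    b = (1 - std::cos(th)) / th2;
  }
  for (int i = 0; i < 9; ++i) R[i] = a * S[i] + b * S2[i];
  R[0] += 1; R[4] += 1; R[8] += 1;
}

static void rot_log(const double* R, double* q) {
  double c = (R[0] + R[4] + R[8] - 1) / 2;
  if (c > 1) c = 1; if (c < -1) c = -1;
  double th = std::acos(c);
  double w[3] = {(R[5] - R[7]) / 2, (R[6] - R[2]) / 2, (R[1] - R[3]) / 2};
  double f;
  if (th < 1e-7) f = 1 + th * th / 6;
  else if (th > M_PI - 1e-5) {
    // symmetric-part fallback (rare in practice: per-solve increments
    // are small); mirror of the R reference
    double B0 = (R[0] + 1) / 2, B4 = (R[4] + 1) / 2, B8 = (R[8] + 1) / 2;
    double ax[3] = {std::sqrt(B0 > 0 ? B0 : 0), std::sqrt(B4 > 0 ? B4 : 0),
                    std::sqrt(B8 > 0 ? B8 : 0)};
    double s0 = R[5] - R[7], s1 = R[6] - R[2], s2 = R[1] - R[3];
    if (s0 < 0) ax[0] = -ax[0];
    if (s1 < 0) ax[1] = -ax[1];
    if (s2 < 0) ax[2] = -ax[2];
    double n = std::sqrt(dot3(ax, ax));
    if (n < 1e-12) { q[0] = th; q[1] = 0; q[2] = 0; return; }
    q[0] = ax[0] / n * th; q[1] = ax[1] / n * th; q[2] = ax[2] / n * th;
    return;
  } else f = th / std::sin(th);
  q[0] = w[0] * f; q[1] = w[1] * f; q[2] = w[2] * f;
}

static void so3_jacl(const double* q, double* J) {
  double th2 = dot3(q, q);
  double S[9] = {0, q[2], -q[1], -q[2], 0, q[0], q[1], -q[0], 0};
  double S2[9];
  matmul(S, S, S2);
  double a, b;
  if (th2 < 1e-16) { a = 0.5; b = 1.0 / 6.0; }
  else {
    double th = std::sqrt(th2);
    a = (1 - std::cos(th)) / th2;
    b = (th - std::sin(th)) / (th2 * th);
  }
  for (int i = 0; i < 9; ++i) J[i] = a * S[i] + b * S2[i];
  J[0] += 1; J[4] += 1; J[8] += 1;
}

static void so3_jacl_inv(const double* q, double* J) {
  double th2 = dot3(q, q);
  double S[9] = {0, q[2], -q[1], -q[2], 0, q[0], q[1], -q[0], 0};
  double S2[9];
  matmul(S, S, S2);
  double b;
  if (th2 < 1e-16) b = 1.0 / 12.0;
  else {
    double th = std::sqrt(th2);
    b = 1.0 / th2 - (1 + std::cos(th)) / (2 * th * std::sin(th));
  }
  for (int i = 0; i < 9; ++i) J[i] = -0.5 * S[i] + b * S2[i];
  J[0] += 1; J[4] += 1; J[8] += 1;
}

// [[Rcpp::export(name = ".energy_grad_cpp")]]
List energy_grad_cpp(List pack, NumericMatrix U, bool want_grad) {
  NumericMatrix Rstart = pack["Rstart"];   // 17 x 9
  NumericMatrix pstart = pack["pstart"];   // 17 x 3
  int has_rod = as<int>(pack["has_rod"]);
  int rod_free = as<int>(pack["rod_free"]);
  NumericVector rodR0 = pack["rodR"], rodt0 = pack["rodt"];

  // current state
  double Rb[18][9], pb[18][3], Jl[18][9];
  bool needJ[18];
  for (int i = 0; i < 17; ++i) {
    double th[3] = {U(i, 3), U(i, 4), U(i, 5)};
    double Rinc[9];
    rot_exp(th, Rinc);
    double R0[9];
    for (int k = 0; k < 9; ++k) R0[k] = Rstart(i, k);
    matmul(Rinc, R0, Rb[i]);
    for (int k = 0; k < 3; ++k) pb[i][k] = pstart(i, k) + U(i, k);
    needJ[i] = true;
  }
  double rodR[9], rodt[3];
  if (has_rod) {
    if (rod_free) {
      double th[3] = {U(17, 3), U(17, 4), U(17, 5)};
      double Rinc[9];
      rot_exp(th, Rinc);
      double R0[9];
      for (int k = 0; k < 9; ++k) R0[k] = rodR0[k];
      matmul(Rinc, R0, rodR);
      for (int k = 0; k < 3; ++k) rodt[k] = rodt0[k] + U(17, k);
    } else {
      for (int k = 0; k < 9; ++k) rodR[k] = rodR0[k];
      for (int k = 0; k < 3; ++k) rodt[k] = rodt0[k];
    }
  }
  if (want_grad)
    for (int i = 0; i < 18; ++i) {
      double th[3] = {U(i, 3), U(i, 4), U(i, 5)};
      so3_jacl(th, Jl[i]);
    }

  double E = 0;
  NumericMatrix G(18, 6);
  double TQ[18][3];
  for (int i = 0; i < 18; ++i) TQ[i][0] = TQ[i][1] = TQ[i][2] = 0;

  // ---- discs
  IntegerVector dia = pack["disc_ia"], dib = pack["disc_ib"];
  NumericMatrix drup = pack["disc_rup"], drlo = pack["disc_rlo"],
                ddt0 = pack["disc_dt0"], dQ0 = pack["disc_Q0"],
                dK = pack["disc_K"];
  int nd = dia.size();
  for (int d = 0; d < nd; ++d) {
    int ia = dia[d] - 1, ib = dib[d] - 1;
    double va[3], vb[3], oup[3], olo[3], dvec[3], dt[3];
    double rup[3] = {drup(d, 0), drup(d, 1), drup(d, 2)};
    double rlo[3] = {drlo(d, 0), drlo(d, 1), drlo(d, 2)};
    matvec(Rb[ia], rup, va);
    matvec(Rb[ib], rlo, vb);
    for (int k = 0; k < 3; ++k) {
      oup[k] = pb[ia][k] + va[k];
      olo[k] = pb[ib][k] + vb[k];
      dvec[k] = oup[k] - olo[k];
    }
    matTvec(Rb[ib], dvec, dt);
    for (int k = 0; k < 3; ++k) dt[k] -= ddt0(d, k);
    double Qrel[9], Q0[9], D[9], dr[3];
    matTmul(Rb[ib], Rb[ia], Qrel);
    for (int k = 0; k < 9; ++k) Q0[k] = dQ0(d, k);
    matmulT(Qrel, Q0, D);
    rot_log(D, dr);
    double del[6] = {dt[0], dt[1], dt[2], dr[0], dr[1], dr[2]};
    double W[6];
    for (int k = 0; k < 6; ++k) { W[k] = dK(d, k) * del[k]; E += 0.5 * W[k] * del[k]; }
    if (want_grad) {
      double Fl[3] = {W[0], W[1], W[2]}, Ml[3] = {W[3], W[4], W[5]};
      double Fg[3], Jinv[9], JiTM[3], Mg[3];
      matvec(Rb[ib], Fl, Fg);
      so3_jacl_inv(dr, Jinv);
      matTvec(Jinv, Ml, JiTM);
      matvec(Rb[ib], JiTM, Mg);
      double aa[3], ab[3], ta[3], tb[3];
      for (int k = 0; k < 3; ++k) {
        aa[k] = oup[k] - pb[ia][k];
        ab[k] = oup[k] - pb[ib][k];
      }
      cross(aa, Fg, ta);
      cross(ab, Fg, tb);
      for (int k = 0; k < 3; ++k) {
        G(ia, k) += Fg[k];
        G(ib, k) -= Fg[k];
        TQ[ia][k] += ta[k] + Mg[k];
        TQ[ib][k] -= tb[k] + Mg[k];
      }
    }
  }

  // ---- tension-only ligaments
  IntegerVector liu = pack["lig_iu"], lil = pack["lig_il"];
  NumericMatrix lrup = pack["lig_rup"], lrlo = pack["lig_rlo"];
  NumericVector lk = pack["lig_k"], lL0 = pack["lig_L0"];
  int nl = liu.size();
  for (int l = 0; l < nl; ++l) {
    int ia = liu[l] - 1, ib = lil[l] - 1;
    double ru[3] = {lrup(l, 0), lrup(l, 1), lrup(l, 2)};
    double rl[3] = {lrlo(l, 0), lrlo(l, 1), lrlo(l, 2)};
    double au[3], al[3], pa[3], pbv[3], dv[3];
    matvec(Rb[ia], ru, au);
    matvec(Rb[ib], rl, al);
    for (int k = 0; k < 3; ++k) {
      pa[k] = pb[ia][k] + au[k];
      pbv[k] = pb[ib][k] + al[k];
      dv[k] = pa[k] - pbv[k];
    }
    double L = std::sqrt(dot3(dv, dv));
    double ext = L - lL0[l];
    if (ext <= 0) continue;
    E += 0.5 * lk[l] * ext * ext;
    if (want_grad) {
      double f = lk[l] * ext / L;
      double Fg[3] = {f * dv[0], f * dv[1], f * dv[2]};
      double ta[3], tb[3];
      cross(au, Fg, ta);
      cross(al, Fg, tb);
      for (int k = 0; k < 3; ++k) {
        G(ia, k) += Fg[k];
        G(ib, k) -= Fg[k];
        TQ[ia][k] += ta[k];
        TQ[ib][k] -= tb[k];
      }
    }
  }

  // ---- screw-rod linkages
  IntegerVector lmode = pack["link_mode"], liv = pack["link_iv"],
                lhasQ = pack["link_hasQ"];
  NumericMatrix lrh = pack["link_rhead"], ltg = pack["link_target"],
                lav = pack["link_avec"], lQl = pack["link_Qlock"];
  double kpen = as<double>(pack["penalty_k"]);
  double krot = as<double>(pack["penalty_rot"]);
  NumericVector tether = pack["tether_k"];
  int nk = lmode.size();
  bool any_link = false;
  for (int s = 0; s < nk; ++s) {
    int mode = lmode[s];
    if (mode == 0) continue;
    any_link = true;
    int iv = liv[s] - 1;
    double rh[3] = {lrh(s, 0), lrh(s, 1), lrh(s, 2)};
    double armv[3], ph[3], cl[3], xt[3], dvec[3], Pd[3];
    matvec(Rb[iv], rh, armv);
    for (int k = 0; k < 3; ++k) ph[k] = pb[iv][k] + armv[k];
    for (int k = 0; k < 3; ++k) cl[k] = ltg(s, k);
    matvec(rodR, cl, xt);
    for (int k = 0; k < 3; ++k) {
      xt[k] += rodt[k];
      dvec[k] = ph[k] - xt[k];
    }
    if (mode == 1) { for (int k = 0; k < 3; ++k) Pd[k] = dvec[k]; }
    else if (mode == 2) { Pd[0] = dvec[0]; Pd[1] = dvec[1]; Pd[2] = 0; }
    else {
      double av[3] = {lav(s, 0), lav(s, 1), lav(s, 2)};
      double pr = dot3(dvec, av);
      if (mode == 3) for (int k = 0; k < 3; ++k) Pd[k] = dvec[k] - pr * av[k];
      else for (int k = 0; k < 3; ++k) Pd[k] = pr * av[k];
    }
    if (lhasQ[s]) {
      double Ql[9], RtR[9], D[9], dr[3];
      for (int k = 0; k < 9; ++k) Ql[k] = lQl(s, k);
      matTmul(rodR, Rb[iv], RtR);
      matmulT(RtR, Ql, D);
      rot_log(D, dr);
      E += 0.5 * krot * dot3(dr, dr);
      if (want_grad) {
        double Jinv[9], JiTM[3], Mg[3];
        double Wr[3] = {krot * dr[0], krot * dr[1], krot * dr[2]};
        so3_jacl_inv(dr, Jinv);
        matTvec(Jinv, Wr, JiTM);
        matvec(rodR, JiTM, Mg);
        for (int k = 0; k < 3; ++k) {
          TQ[iv][k] += Mg[k];
          if (rod_free) TQ[17][k] -= Mg[k];
        }
      }
    }
    E += 0.5 * kpen * dot3(Pd, Pd);
    if (want_grad) {
      double Fg[3] = {kpen * Pd[0], kpen * Pd[1], kpen * Pd[2]};
      double tv[3];
      cross(armv, Fg, tv);
      for (int k = 0; k < 3; ++k) {
        G(iv, k) += Fg[k];
        TQ[iv][k] += tv[k];
      }
      if (rod_free) {
        double armr[3] = {xt[0] - rodt[0], xt[1] - rodt[1], xt[2] - rodt[2]};
        double tr[3];
        cross(armr, Fg, tr);
        for (int k = 0; k < 3; ++k) {
          G(17, k) -= Fg[k];
          TQ[17][k] -= tr[k];
        }
      }
    }
  }
  if (has_rod && rod_free && nk > 0) {
    // rod holder spring, recentred at solve start
    for (int k = 0; k < 3; ++k) {
      E += 0.5 * tether[0] * U(17, k) * U(17, k) +
           0.5 * tether[1] * U(17, k + 3) * U(17, k + 3);
      if (want_grad) G(17, k) += tether[0] * U(17, k);
    }
  }
  (void)any_link;

  if (want_grad) {
    for (int i = 0; i < 18; ++i) {
      double out[3];
      matTvec(Jl[i], TQ[i], out);
      for (int k = 0; k < 3; ++k) G(i, k + 3) += out[k];
    }
    if (has_rod && rod_free && nk > 0)
      for (int k = 0; k < 3; ++k) G(17, k + 3) += tether[1] * U(17, k + 3);
  }

  // external generalized moment
  double extM = as<double>(pack["ext_M"]);
  if (extM != 0) {
    int eb = as<int>(pack["ext_body"]) - 1;
    int ec = as<int>(pack["ext_comp"]) - 1;
    E -= extM * U(eb, ec);
    if (want_grad) G(eb, ec) -= extM;
  }

  return List::create(_["E"] = E, _["G"] = G);
}
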