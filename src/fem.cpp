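#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Large-deformation Neo-Hookean finite elements on bilinear quadrilaterals,
// axisymmetric (r, z) or plane strain, total Lagrangian.
//
// Discrete energy per element:
//   E = sum_gp w_gp C10 (J^{-2/3} I1 - 3)  +  V_e K/2 (Jc - 1)^2
// with the isochoric term at 2x2 Gauss points and the volumetric term at the
// element centroid (mean-dilatation / selective treatment, which prevents
// volumetric locking of fully integrated quads near incompressibility).
// Residual = exact analytic gradient of this energy; tangent = central finite
// differences of the analytic gradient at Gauss-point level (machine
// accurate, so Newton retains quadratic convergence).
//
// Deformation gradient components are ordered (Frr, Frz, Fzr, Fzz, Ftt).

static const double GP = 0.5773502691896257645091488;

struct ElemGeom {
  double dNdR[4][4], dNdZ[4][4], N[4][4], w[4], Rgp[4];
  double dNdR0[4], dNdZ0[4], N0[4], R0, V;  // centroid data, ref volume
  bool ok;
};

static void shape(double xi, double eta, double *N, double *dxi, double *deta) {
  const double sx[4] = {-1, 1, 1, -1}, sy[4] = {-1, -1, 1, 1};
  for (int a = 0; a < 4; ++a) {
    N[a] = 0.25 * (1 + sx[a] * xi) * (1 + sy[a] * eta);
    dxi[a] = 0.25 * sx[a] * (1 + sy[a] * eta);
    deta[a] = 0.25 * sy[a] * (1 + sx[a] * xi);
  }
}

static bool geom_at(const double *Re, const double *Ze, double xi, double eta,
                    bool axisym, double *N, double *dNdR, double *dNdZ,
                    double *wdet, double *Rgp) {
  double dxi[4], deta[4];
  shape(xi, eta, N, dxi, deta);
  double j11 = 0, j12 = 0, j21 = 0, j22 = 0, R = 0;
  for (int a = 0; a < 4; ++a) {
    j11 += dxi[a] * Re[a];  j12 += deta[a] * Re[a];
    j21 += dxi[a] * Ze[a];  j22 += deta[a] * Ze[a];
    R += N[a] * Re[a];
  }
  const double det = j11 * j22 - j12 * j21;
  if (det <= 0) return false;
  for (int a = 0; a < 4; ++a) {
    dNdR[a] = ( j22 * dxi[a] - j21 * deta[a]) / det;
    dNdZ[a] = (-j12 * dxi[a] + j11 * deta[a]) / det;
  }
  *Rgp = R;
  *wdet = det * (axisym ? 2.0 * M_PI * R : 1.0);
  return true;
}

static ElemGeom elem_geom(const double *Re, const double *Ze, bool axisym) {
  ElemGeom g;
  g.ok = true;
  g.V = 0;
  const double xi[4] = {-GP, GP, GP, -GP}, eta[4] = {-GP, -GP, GP, GP};
  for (int q = 0; q < 4; ++q) {
    double wdet;
    if (!geom_at(Re, Ze, xi[q], eta[q], axisym, g.N[q], g.dNdR[q], g.dNdZ[q],
                 &wdet, &g.Rgp[q])) { g.ok = false; return g; }
    g.w[q] = wdet;  // gauss weights are 1
    g.V += wdet;
  }
  double wdet0;
  if (!geom_at(Re, Ze, 0, 0, axisym, g.N0, g.dNdR0, g.dNdZ0, &wdet0, &g.R0))
    g.ok = false;
  return g;
}

// F (5 components) at a quadrature point from element displacements
static void def_grad(const double *dNdR, const double *dNdZ, const double *N,
                     double Rgp, const double *ue, bool axisym, double *F) {
  F[0] = 1; F[1] = 0; F[2] = 0; F[3] = 1; F[4] = 1;
  for (int a = 0; a < 4; ++a) {
    const double ur = ue[2 * a], uz = ue[2 * a + 1];
    F[0] += dNdR[a] * ur;
    F[1] += dNdZ[a] * ur;
    F[2] += dNdR[a] * uz;
    F[3] += dNdZ[a] * uz;
    if (axisym) F[4] += N[a] / Rgp * ur;
  }
}

static inline double detF(const double *F) {
  return (F[0] * F[3] - F[1] * F[2]) * F[4];
}

// dW_iso/dF for W_iso = C10 (J^{-2/3} I1 - 3); returns false if J <= 0
static bool p_iso(const double *F, double C10, double *P) {
  const double det2 = F[0] * F[3] - F[1] * F[2];
  const double J = det2 * F[4];
  if (J <= 0 || det2 <= 0) return false;
  const double I1 = F[0]*F[0] + F[1]*F[1] + F[2]*F[2] + F[3]*F[3] + F[4]*F[4];
  const double Jm23 = std::pow(J, -2.0 / 3.0);
  const double FiT[5] = { F[3]/det2, -F[2]/det2, -F[1]/det2, F[0]/det2,
                          1.0 / F[4] };
  const double c = C10 * Jm23;
  for (int k = 0; k < 5; ++k)
    P[k] = c * (2.0 * F[k] - (2.0 / 3.0) * I1 * FiT[k]);
  return true;
}

// d(K/2 (J-1)^2)/dF = K (J-1) J F^{-T}
static bool g_vol(const double *F, double Kb, double *G) {
  const double det2 = F[0] * F[3] - F[1] * F[2];
  const double J = det2 * F[4];
  if (J <= 0 || det2 <= 0) return false;
  const double c = Kb * (J - 1.0) * J;
  G[0] =  c * F[3] / det2;
  G[1] = -c * F[2] / det2;
  G[2] = -c * F[1] / det2;
  G[3] =  c * F[0] / det2;
  G[4] =  c / F[4];
  return true;
}

// central finite-difference Jacobian of an analytic 5-vector gradient
template <typename Fn>
static bool fd_jac(const double *F, int ncomp, Fn fn, double A[5][5]) {
  double Fp[5], Fm[5], Pp[5], Pm[5];
  for (int k = 0; k < ncomp; ++k) {
    const double h = 1e-6 * std::max(1.0, std::fabs(F[k]));
    for (int j = 0; j < 5; ++j) { Fp[j] = F[j]; Fm[j] = F[j]; }
    Fp[k] += h; Fm[k] -= h;
    if (!fn(Fp, Pp) || !fn(Fm, Pm)) return false;
    for (int j = 0; j < ncomp; ++j) A[j][k] = (Pp[j] - Pm[j]) / (2.0 * h);
  }
  return true;
}

// Gmat: rows = F components, cols = element dofs (r1 z1 r2 z2 r3 z3 r4 z4)
static void build_G(const double *dNdR, const double *dNdZ, const double *N,
                    double Rgp, bool axisym, double G[5][8]) {
  for (int j = 0; j < 5; ++j)
    for (int c = 0; c < 8; ++c) G[j][c] = 0;
  for (int a = 0; a < 4; ++a) {
    G[0][2 * a] = dNdR[a];
    G[1][2 * a] = dNdZ[a];
    G[2][2 * a + 1] = dNdR[a];
    G[3][2 * a + 1] = dNdZ[a];
    if (axisym) G[4][2 * a] = N[a] / Rgp;
  }
}

// [[Rcpp::export(name = ".fem_assemble_cpp")]]
List fem_assemble_cpp(NumericMatrix nodes, IntegerMatrix elems,
                      NumericVector u, NumericVector C10, NumericVector Kb,
                      bool axisym, bool want_tangent) {
  const int nn = nodes.nrow(), ne = elems.nrow();
  const int ncomp = axisym ? 5 : 4;
  NumericVector fint(2 * nn);
  std::vector<int> ti, tj;
  std::vector<double> tv;
  if (want_tangent) { ti.reserve(ne * 64); tj.reserve(ne * 64); tv.reserve(ne * 64); }
  double Jmin = R_PosInf;
  bool bad = false;

  for (int e = 0; e < ne && !bad; ++e) {
    double Re[4], Ze[4], ue[8];
    int gdof[8];
    for (int a = 0; a < 4; ++a) {
      const int nd = elems(e, a) - 1;
      Re[a] = nodes(nd, 0);
      Ze[a] = nodes(nd, 1);
      ue[2 * a] = u[2 * nd];
      ue[2 * a + 1] = u[2 * nd + 1];
      gdof[2 * a] = 2 * nd;
      gdof[2 * a + 1] = 2 * nd + 1;
    }
    const ElemGeom g = elem_geom(Re, Ze, axisym);
    if (!g.ok) { bad = true; Jmin = -1; break; }
    const double c10 = C10[e], kb = Kb[e];
    double fe[8] = {0, 0, 0, 0, 0, 0, 0, 0};
    double Ke[8][8];
    if (want_tangent)
      for (int i = 0; i < 8; ++i) for (int j = 0; j < 8; ++j) Ke[i][j] = 0;

    // centroid volumetric term
    double F0[5], G0[5][8], gv[5];
    def_grad(g.dNdR0, g.dNdZ0, g.N0, g.R0, ue, axisym, F0);
    const double Jc = detF(F0);
    if (Jc < Jmin) Jmin = Jc;
    if (Jc <= 0) continue;  // caller rejects via Jmin
    build_G(g.dNdR0, g.dNdZ0, g.N0, g.R0, axisym, G0);
    if (!g_vol(F0, kb, gv)) continue;
    for (int c = 0; c < 8; ++c)
      for (int j = 0; j < ncomp; ++j)
        fe[c] += g.V * gv[j] * G0[j][c];
    if (want_tangent) {
      double Av[5][5];
      auto gfun = [kb](const double *F, double *G) { return g_vol(F, kb, G); };
      if (fd_jac(F0, ncomp, gfun, Av)) {
        for (int i = 0; i < 8; ++i)
          for (int j = 0; j < 8; ++j) {
            double s = 0;
            for (int a = 0; a < ncomp; ++a)
              for (int b = 0; b < ncomp; ++b)
                s += G0[a][i] * Av[a][b] * G0[b][j];
            Ke[i][j] += g.V * s;
          }
      }
    }

    // isochoric term at the 2x2 Gauss points
    for (int q = 0; q < 4; ++q) {
      double F[5], P[5], G[5][8];
      def_grad(g.dNdR[q], g.dNdZ[q], g.N[q], g.Rgp[q], ue, axisym, F);
      const double J = detF(F);
      if (J < Jmin) Jmin = J;
      if (J <= 0) continue;
      if (!p_iso(F, c10, P)) continue;
      build_G(g.dNdR[q], g.dNdZ[q], g.N[q], g.Rgp[q], axisym, G);
      for (int c = 0; c < 8; ++c)
        for (int j = 0; j < ncomp; ++j)
          fe[c] += g.w[q] * P[j] * G[j][c];
      if (want_tangent) {
        double A[5][5];
        auto pfun = [c10](const double *Fv, double *Pv) {
          return p_iso(Fv, c10, Pv);
        };
        if (fd_jac(F, ncomp, pfun, A)) {
          for (int i = 0; i < 8; ++i)
            for (int j = 0; j < 8; ++j) {
              double s = 0;
              for (int a = 0; a < ncomp; ++a)
                for (int b = 0; b < ncomp; ++b)
                  s += G[a][i] * A[a][b] * G[b][j];
              Ke[i][j] += g.w[q] * s;
            }
        }
      }
    }

    for (int c = 0; c < 8; ++c) fint[gdof[c]] += fe[c];
    if (want_tangent) {
      for (int i = 0; i < 8; ++i)
        for (int j = 0; j < 8; ++j) {
          ti.push_back(gdof[i] + 1);
          tj.push_back(gdof[j] + 1);
          tv.push_back(Ke[i][j]);
        }
    }
  }
  return List::create(_["fint"] = fint, _["ti"] = wrap(ti), _["tj"] = wrap(tj),
                      _["tv"] = wrap(tv), _["Jmin"] = Jmin);
}

// Total strain energy of the discrete model (used by gradient-check tests).
// [[Rcpp::export(name = ".fem_energy_cpp")]]
double fem_energy_cpp(NumericMatrix nodes, IntegerMatrix elems,
                      NumericVector u, NumericVector C10, NumericVector Kb,
                      bool axisym) {
  const int ne = elems.nrow();
  double E = 0;
  for (int e = 0; e < ne; ++e) {
    double Re[4], Ze[4], ue[8];
    for (int a = 0; a < 4; ++a) {
      const int nd = elems(e, a) - 1;
      Re[a] = nodes(nd, 0);
      Ze[a] = nodes(nd, 1);
      ue[2 * a] = u[2 * nd];
      ue[2 * a + 1] = u[2 * nd + 1];
    }
    const ElemGeom g = elem_geom(Re, Ze, axisym);
    if (!g.ok) return NA_REAL;
    double F0[5];
    def_grad(g.dNdR0, g.dNdZ0, g.N0, g.R0, ue, axisym, F0);
    const double Jc = detF(F0);
    if (Jc <= 0) return NA_REAL;
    E += g.V * Kb[e] / 2.0 * (Jc - 1.0) * (Jc - 1.0);
    for (int q = 0; q < 4; ++q) {
      double F[5];
      def_grad(g.dNdR[q], g.dNdZ[q], g.N[q], g.Rgp[q], ue, axisym, F);
      const double J = detF(F);
      if (J <= 0) return NA_REAL;
      const double I1 = F[0]*F[0] + F[1]*F[1] + F[2]*F[2] + F[3]*F[3] + F[4]*F[4];
      E += g.w[q] * C10[e] * (std::pow(J, -2.0 / 3.0) * I1 - 3.0);
    }
  }
  return E;
}

// Cauchy stresses at the 2x2 Gauss points of every element.
// Columns: elem, gp, R0, Z0, r, z, J, Jc, s_rr, s_rz, s_zz, s_tt, Frr, Ftt.
// sigma = J^{-1} P_iso F^T + K (Jc - 1) I  (element-constant pressure).
// Frr and Ftt allow conversion of the axial Cauchy stress to engineering
// traction on a flat z-normal surface (factor Frr * Ftt, Nanson's relation).
// [[Rcpp::export(name = ".fem_stress_cpp")]]
NumericMatrix fem_stress_cpp(NumericMatrix nodes, IntegerMatrix elems,
                             NumericVector u, NumericVector C10,
                             NumericVector Kb, bool axisym) {
  const int ne = elems.nrow();
  NumericMatrix out(ne * 4, 14);
  for (int e = 0; e < ne; ++e) {
    double Re[4], Ze[4], ue[8];
    for (int a = 0; a < 4; ++a) {
      const int nd = elems(e, a) - 1;
      Re[a] = nodes(nd, 0);
      Ze[a] = nodes(nd, 1);
      ue[2 * a] = u[2 * nd];
      ue[2 * a + 1] = u[2 * nd + 1];
    }
    const ElemGeom g = elem_geom(Re, Ze, axisym);
    double F0[5];
    def_grad(g.dNdR0, g.dNdZ0, g.N0, g.R0, ue, axisym, F0);
    const double Jc = detF(F0);
    const double p = Kb[e] * (Jc - 1.0);
    for (int q = 0; q < 4; ++q) {
      double F[5], P[5];
      def_grad(g.dNdR[q], g.dNdZ[q], g.N[q], g.Rgp[q], ue, axisym, F);
      const double J = detF(F);
      const int row = e * 4 + q;
      double r = 0, z = 0, R0q = 0, Z0q = 0;
      for (int a = 0; a < 4; ++a) {
        R0q += g.N[q][a] * Re[a];
        Z0q += g.N[q][a] * Ze[a];
        r += g.N[q][a] * (Re[a] + ue[2 * a]);
        z += g.N[q][a] * (Ze[a] + ue[2 * a + 1]);
      }
      out(row, 0) = e + 1;
      out(row, 1) = q + 1;
      out(row, 2) = R0q;  out(row, 3) = Z0q;
      out(row, 4) = r;    out(row, 5) = z;
      out(row, 6) = J;    out(row, 7) = Jc;
      out(row, 12) = F[0];
      out(row, 13) = F[4];
      if (J <= 0 || !p_iso(F, C10[e], P)) {
        out(row, 8) = NA_REAL; out(row, 9) = NA_REAL;
        out(row, 10) = NA_REAL; out(row, 11) = NA_REAL;
        continue;
      }
      // sigma = (1/J) P F^T + p I (2x2 block and hoop)
      const double s_rr = (P[0] * F[0] + P[1] * F[1]) / J + p;
      const double s_rz = (P[0] * F[2] + P[1] * F[3]) / J;
      const double s_zz = (P[2] * F[2] + P[3] * F[3]) / J + p;
      const double s_tt = P[4] * F[4] / J + p;
      out(row, 8) = s_rr;
      out(row, 9) = s_rz;
      out(row, 10) = s_zz;
      out(row, 11) = s_tt;
    }
  }
  colnames(out) = CharacterVector::create("elem", "gp", "R0", "Z0", "r", "z",
                                          "J", "Jc", "s_rr", "s_rz", "s_zz",
                                          "s_tt", "Frr", "Ftt");
  return out;
}
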