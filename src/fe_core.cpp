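// Total-Lagrangian finite-element core: 8-node hexahedra with a modified
// Mooney-Rivlin material (isotropic Mooney-Rivlin + exponential I1 term +
// exponential fiber I4 term) and a volumetric penalty integrated with
// selective reduced integration (deviatoric terms at 2x2x2 Gauss points,
// penalty at the element centre) to avoid volumetric locking. Cavity
// pressures are follower loads with their exact load stiffness; bands are
// geometrically exact tension-only cable elements with an evolving
// zero-stress length. Units: mm, kPa => nodal forces in mN.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const double GP = 0.577350269189625764509148780502;
// fraction of the volumetric penalty integrated at full order to control
// hourglass modes; the rest is reduced-integrated at the element centre
static double KSTAB = 0.1;

// [[Rcpp::export]]
void fe_set_kstab(double v) { KSTAB = v; }

struct MatPt {
  double W1, W2, W4;     // dW/dI1, dW/dI2, dW/dI4
  double W11, W44;       // second derivatives
};

static inline MatPt mr_derivs(const rowvec& mp, double I1, double I4) {
  // mp: c1 c2 D1 D2 K1 K2 kappa
  MatPt d;
  double c1 = mp[0], c2 = mp[1], D1 = mp[2], D2 = mp[3], K1 = mp[4], K2 = mp[5];
  double ex = (D1 > 0.0) ? std::exp(D2 * (I1 - 3.0)) : 0.0;
  d.W1 = c1 + D1 * D2 * ex;
  d.W11 = D1 * D2 * D2 * ex;
  d.W2 = c2;
  d.W4 = 0.0; d.W44 = 0.0;
  if (K1 > 0.0 && I4 > 1.0) {
    double q = I4 - 1.0;
    double ea = std::exp(K2 * q * q);
    d.W4 = 2.0 * K1 * q * ea;
    d.W44 = 2.0 * K1 * ea * (1.0 + 2.0 * K2 * q * q);
  }
  return d;
}

static void shape_hex(double xi, double eta, double zeta,
                      vec& N, mat& dN) {
  // VTK-style corner numbering: bottom (z-) quad then top quad
  static const double sg[8][3] = {
    {-1,-1,-1},{ 1,-1,-1},{ 1, 1,-1},{-1, 1,-1},
    {-1,-1, 1},{ 1,-1, 1},{ 1, 1, 1},{-1, 1, 1}};
  N.set_size(8); dN.set_size(8, 3);
  for (int a = 0; a < 8; ++a) {
    double sx = sg[a][0], sy = sg[a][1], sz = sg[a][2];
    N[a] = 0.125 * (1 + sx * xi) * (1 + sy * eta) * (1 + sz * zeta);
    dN(a, 0) = 0.125 * sx * (1 + sy * eta) * (1 + sz * zeta);
    dN(a, 1) = 0.125 * sy * (1 + sx * xi) * (1 + sz * zeta);
    dN(a, 2) = 0.125 * sz * (1 + sx * xi) * (1 + sy * eta);
  }
}

// Voigt pair indices: 0:(0,0) 1:(1,1) 2:(2,2) 3:(0,1) 4:(1,2) 5:(0,2)
static const int VI[6] = {0, 1, 2, 0, 1, 0};
static const int VJ[6] = {0, 1, 2, 1, 2, 2};

static inline void build_B(const mat& F, const mat& dNdX, mat& B) {
  // B (6 x 24): delta E_voigt (engineering shear) = B * delta u
  B.zeros(6, 24);
  for (int a = 0; a < 8; ++a) {
    double g0 = dNdX(a, 0), g1 = dNdX(a, 1), g2 = dNdX(a, 2);
    for (int k = 0; k < 3; ++k) {
      int c = 3 * a + k;
      B(0, c) = F(k, 0) * g0;
      B(1, c) = F(k, 1) * g1;
      B(2, c) = F(k, 2) * g2;
      B(3, c) = F(k, 0) * g1 + F(k, 1) * g0;
      B(4, c) = F(k, 1) * g2 + F(k, 2) * g1;
      B(5, c) = F(k, 0) * g2 + F(k, 2) * g0;
    }
  }
}

static inline void dev_tangent(const MatPt& d, const mat& C, const vec& nf,
                               mat& D) {
  // D_pq = C_ijkl (4 d2W/dCdC) at representative Voigt indices
  D.zeros(6, 6);
  double a1 = 4.0 * d.W11;
  double a2 = 4.0 * d.W2;
  vec np(6);
  for (int p = 0; p < 6; ++p) np[p] = nf[VI[p]] * nf[VJ[p]];
  for (int p = 0; p < 6; ++p) {
    for (int q = 0; q < 6; ++q) {
      double v = 0.0;
      bool pn = p < 3, qn = q < 3;
      if (pn && qn) {
        v += a1;
        v += a2 * (1.0 - (p == q ? 1.0 : 0.0));
      }
      if (!pn && p == q) v += -2.0 * d.W2;  // a2 * (0 - 1/2)
      v += 4.0 * d.W44 * np[p] * np[q];
      D(p, q) += v;
    }
  }
}

static inline void vol_tangent(double kappa, double p0, double J,
                               const mat& Ci, mat& D) {
  // S_vol = (kappa (J-1) J - p0) C^{-1}
  double kv1 = kappa * (2.0 * J - 1.0) * J;
  double kv2 = kappa * (J * J - J) - p0;
  D.zeros(6, 6);
  for (int p = 0; p < 6; ++p) {
    int i = VI[p], j = VJ[p];
    for (int q = 0; q < 6; ++q) {
      int k = VI[q], l = VJ[q];
      D(p, q) = kv1 * Ci(i, j) * Ci(k, l)
        - kv2 * (Ci(i, k) * Ci(j, l) + Ci(i, l) * Ci(j, k));
    }
  }
}

static inline mat skew3(const vec& v) {
  mat s(3, 3, fill::zeros);
  s(0, 1) = -v[2]; s(0, 2) = v[1];
  s(1, 0) = v[2];  s(1, 2) = -v[0];
  s(2, 0) = -v[1]; s(2, 1) = v[0];
  return s;
}

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List fe_pattern(IntegerMatrix elems, IntegerMatrix faces,
                NumericMatrix bands, IntegerVector dofmap) {
  // canonical triplet order: elements, then faces, then bands; entries with
  // a fixed dof are emitted as (0,0) and skipped by the assembler
  std::vector<int> ti, tj;
  int M = elems.nrow();
  for (int e = 0; e < M; ++e)
    for (int a = 0; a < 8; ++a) for (int i = 0; i < 3; ++i) {
      int r = dofmap[3 * (elems(e, a) - 1) + i];
      for (int b = 0; b < 8; ++b) for (int j = 0; j < 3; ++j) {
        int c = dofmap[3 * (elems(e, b) - 1) + j];
        ti.push_back(r > 0 && c > 0 ? r : 0);
        tj.push_back(r > 0 && c > 0 ? c : 0);
      }
    }
  for (int f = 0; f < faces.nrow(); ++f)
    for (int a = 0; a < 4; ++a) for (int i = 0; i < 3; ++i) {
      int r = dofmap[3 * (faces(f, a) - 1) + i];
      for (int b = 0; b < 4; ++b) for (int j = 0; j < 3; ++j) {
        int c = dofmap[3 * (faces(f, b) - 1) + j];
        ti.push_back(r > 0 && c > 0 ? r : 0);
        tj.push_back(r > 0 && c > 0 ? c : 0);
      }
    }
  for (int bn = 0; bn < bands.nrow(); ++bn) {
    int nd[2] = {(int)bands(bn, 0) - 1, (int)bands(bn, 1) - 1};
    for (int a = 0; a < 2; ++a) for (int i = 0; i < 3; ++i) {
      int r = dofmap[3 * nd[a] + i];
      for (int b = 0; b < 2; ++b) for (int j = 0; j < 3; ++j) {
        int c = dofmap[3 * nd[b] + j];
        ti.push_back(r > 0 && c > 0 ? r : 0);
        tj.push_back(r > 0 && c > 0 ? c : 0);
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj));
}

// [[Rcpp::export]]
List fe_assemble(NumericMatrix nodes_, IntegerMatrix elems,
                 NumericMatrix disp_, NumericMatrix matpar_,
                 NumericMatrix fiber_, IntegerMatrix faces,
                 NumericVector face_p, NumericMatrix bands,
                 IntegerVector dofmap, IntegerVector xmap, int nnz,
                 bool want_matrix) {
  int N = nodes_.nrow(), M = elems.nrow();
  mat nodes(nodes_.begin(), N, 3, false);
  mat disp(disp_.begin(), N, 3, false);
  mat matpar(matpar_.begin(), M, matpar_.ncol(), false);
  mat fiber(fiber_.begin(), M, 3, false);
  vec fint(3 * N, fill::zeros), fext(3 * N, fill::zeros);
  vec xval(nnz, fill::zeros);
  size_t tcount = 0;  // running canonical triplet index
  bool ok = true;

  size_t tmax = xmap.size();
  auto push = [&](int r, int c, double v) {
    // r,c already reduced (from pattern); use xmap by running index
    if (tcount >= tmax) stop("assembly pattern mismatch (bands changed?)");
    int pos = xmap[tcount];
    if (pos > 0) xval[pos - 1] += v;
    ++tcount;
  };

  vec Nsh; mat dN;
  mat Xe(8, 3), ue(8, 3);
  mat B(6, 24), D(6, 6), Ke(24, 24);
  vec fe(24);

  for (int e = 0; e < M && ok; ++e) {
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      Xe.row(a) = nodes.row(n);
      ue.row(a) = disp.row(n);
    }
    rowvec mp = matpar.row(e);
    double kappa = mp[6];
    vec nf = fiber.row(e).t();
    Ke.zeros(); fe.zeros();
    // deviatoric: full 2x2x2 integration
    for (int g = 0; g < 8 && ok; ++g) {
      double xi = (g & 1 ? GP : -GP);
      double eta = (g & 2 ? GP : -GP);
      double zeta = (g & 4 ? GP : -GP);
      shape_hex(xi, eta, zeta, Nsh, dN);
      mat J0 = Xe.t() * dN;
      double detJ0 = det(J0);
      if (detJ0 <= 0) { ok = false; break; }
      mat dNdX = dN * inv(J0);
      mat F = eye(3, 3) + ue.t() * dNdX;
      double J = det(F);
      if (J <= 0) { ok = false; break; }
      mat C = F.t() * F;
      double I1 = trace(C);
      double I4 = as_scalar(nf.t() * C * nf);
      MatPt d = mr_derivs(mp, I1, I4);
      mat S = 2.0 * d.W1 * eye(3, 3) + 2.0 * d.W2 * (I1 * eye(3, 3) - C)
        + 2.0 * d.W4 * (nf * nf.t());
      // hydrostatic compensation and a stabilizing fraction of the penalty
      // are integrated at full order; the bulk of the penalty at the centre
      double p0 = 2.0 * (mp[0] + mp[2] * mp[3]) + 4.0 * mp[1];
      double kth = KSTAB * kappa;
      mat Ci = inv_sympd(0.5 * (C + C.t()));
      S += (kth * (J - 1.0) * J - p0) * Ci;
      double w = detJ0;
      vec Sv = {S(0,0), S(1,1), S(2,2), S(0,1), S(1,2), S(0,2)};
      build_B(F, dNdX, B);
      fe += w * (B.t() * Sv);
      if (want_matrix) {
        dev_tangent(d, C, nf, D);
        mat Dv(6, 6);
        vol_tangent(kth, p0, J, Ci, Dv);
        D += Dv;
        Ke += w * (B.t() * D * B);
        // geometric part
        mat SgN = S * dNdX.t();          // 3 x 8
        mat gss = dNdX * SgN;            // 8 x 8: g_a . S g_b
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b) {
            double v = w * gss(a, b);
            Ke(3*a, 3*b) += v; Ke(3*a+1, 3*b+1) += v; Ke(3*a+2, 3*b+2) += v;
          }
      }
    }
    // remaining penalty fraction: single centre point (selective reduced
    // integration keeps the near-incompressible response locking-free)
    if (ok && kappa > 0) {
      shape_hex(0.0, 0.0, 0.0, Nsh, dN);
      mat J0 = Xe.t() * dN;
      double detJ0 = det(J0);
      if (detJ0 <= 0) ok = false;
      else {
        double w = 8.0 * detJ0;
        mat dNdX = dN * inv(J0);
        mat F = eye(3, 3) + ue.t() * dNdX;
        double J = det(F);
        if (J <= 0) ok = false;
        else {
          mat C = F.t() * F;
          mat Ci = inv_sympd(0.5 * (C + C.t()));
          double kc = (1.0 - KSTAB) * kappa;
          mat S = kc * (J - 1.0) * J * Ci;
          vec Sv = {S(0,0), S(1,1), S(2,2), S(0,1), S(1,2), S(0,2)};
          build_B(F, dNdX, B);
          fe += w * (B.t() * Sv);
          if (want_matrix) {
            vol_tangent(kc, 0.0, J, Ci, D);
            Ke += w * (B.t() * D * B);
            mat SgN = S * dNdX.t();
            mat gss = dNdX * SgN;
            for (int a = 0; a < 8; ++a)
              for (int b = 0; b < 8; ++b) {
                double v = w * gss(a, b);
                Ke(3*a, 3*b) += v; Ke(3*a+1, 3*b+1) += v; Ke(3*a+2, 3*b+2) += v;
              }
          }
        }
      }
    }
    if (!ok) break;
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) fint[3 * n + i] += fe[3 * a + i];
    }
    if (want_matrix) {
      for (int a = 0; a < 8; ++a) for (int i = 0; i < 3; ++i)
        for (int b = 0; b < 8; ++b) for (int j = 0; j < 3; ++j)
          push(0, 0, Ke(3 * a + i, 3 * b + j));
    } else {
      tcount += 24 * 24;
    }
  }

  // follower pressure on cavity faces (2x2 Gauss)
  if (ok) {
    mat dNf(4, 2);
    for (int f = 0; f < faces.nrow(); ++f) {
      double p = face_p[f];
      mat xf(4, 3);
      for (int a = 0; a < 4; ++a) {
        int n = faces(f, a) - 1;
        xf.row(a) = nodes.row(n) + disp.row(n);
      }
      mat Kf(12, 12, fill::zeros);
      vec ff(12, fill::zeros);
      for (int g = 0; g < 4; ++g) {
        double xi = (g & 1 ? GP : -GP), eta = (g & 2 ? GP : -GP);
        vec Nq = {0.25*(1-xi)*(1-eta), 0.25*(1+xi)*(1-eta),
                  0.25*(1+xi)*(1+eta), 0.25*(1-xi)*(1+eta)};
        dNf(0,0) = -0.25*(1-eta); dNf(0,1) = -0.25*(1-xi);
        dNf(1,0) =  0.25*(1-eta); dNf(1,1) = -0.25*(1+xi);
        dNf(2,0) =  0.25*(1+eta); dNf(2,1) =  0.25*(1+xi);
        dNf(3,0) = -0.25*(1+eta); dNf(3,1) =  0.25*(1-xi);
        vec gxi = xf.t() * dNf.col(0);
        vec geta = xf.t() * dNf.col(1);
        vec an = cross(gxi, geta);
        for (int a = 0; a < 4; ++a)
          ff.subvec(3*a, 3*a+2) += p * Nq[a] * an;
        if (want_matrix) {
          mat sgxi = skew3(gxi), sgeta = skew3(geta);
          for (int a = 0; a < 4; ++a)
            for (int b = 0; b < 4; ++b) {
              mat blk = p * Nq[a] * (-dNf(b,0) * sgeta + dNf(b,1) * sgxi);
              Kf.submat(3*a, 3*b, 3*a+2, 3*b+2) += blk;
            }
        }
      }
      for (int a = 0; a < 4; ++a) {
        int n = faces(f, a) - 1;
        for (int i = 0; i < 3; ++i) fext[3 * n + i] += ff[3 * a + i];
      }
      if (want_matrix) {
        // K = d(fint - fext)/du => subtract load stiffness
        for (int a = 0; a < 4; ++a) for (int i = 0; i < 3; ++i)
          for (int b = 0; b < 4; ++b) for (int j = 0; j < 3; ++j)
            push(0, 0, -Kf(3 * a + i, 3 * b + j));
      } else {
        tcount += 12 * 12;
      }
    }
  }

  // band cable elements: columns a, b, L0, c1, area, tension_only
  if (ok) {
    for (int bn = 0; bn < bands.nrow(); ++bn) {
      int na = (int)bands(bn, 0) - 1, nb = (int)bands(bn, 1) - 1;
      double L0 = bands(bn, 2), c1 = bands(bn, 3), A0 = bands(bn, 4);
      bool tonly = bands(bn, 5) > 0.5;
      vec xa = nodes.row(na).t() + disp.row(na).t();
      vec xb = nodes.row(nb).t() + disp.row(nb).t();
      vec dv = xb - xa;
      double l = norm(dv);
      double lam = l / L0;
      bool active = !(tonly && lam <= 1.0) && l > 1e-12;
      vec dir = active ? vec(dv / l) : vec(3, fill::zeros);
      double Nf = 0.0, dNdl = 0.0;
      if (active) {
        // C1-regularized engagement: N = 2 c1 A0 f(lam) s/(s+eps), s=lam-1,
        // so the slack-to-taut transition is smooth and Newton-friendly
        const double eps = 0.02;
        double s = lam - 1.0;
        double f = lam - 1.0 / (lam * lam);
        double fp = 1.0 + 2.0 / (lam * lam * lam);
        double w = s / (s + eps);
        double wp = eps / ((s + eps) * (s + eps));
        Nf = 2.0 * c1 * A0 * f * w;
        dNdl = 2.0 * c1 * A0 * (fp * w + f * wp) / L0;
      }
      for (int i = 0; i < 3; ++i) {
        fint[3 * na + i] += -Nf * dir[i];
        fint[3 * nb + i] += Nf * dir[i];
      }
      if (want_matrix) {
        mat k(3, 3, fill::zeros);
        if (active)
          k = dNdl * (dir * dir.t()) + (Nf / l) * (eye(3,3) - dir * dir.t());
        for (int a = 0; a < 2; ++a) for (int i = 0; i < 3; ++i)
          for (int b = 0; b < 2; ++b) for (int j = 0; j < 3; ++j)
            push(0, 0, (a == b ? 1.0 : -1.0) * k(i, j));
      } else {
        tcount += 36;
      }
    }
  }

  return List::create(
    _["ok"] = ok,
    _["x"] = NumericVector(xval.begin(), xval.end()),
    _["fint"] = NumericVector(fint.begin(), fint.end()),
    _["fext"] = NumericVector(fext.begin(), fext.end()));
}

// [[Rcpp::export]]
List fe_fields(NumericMatrix nodes_, IntegerMatrix elems,
               NumericMatrix disp_, NumericMatrix matpar_,
               NumericMatrix fiber_) {
  int N = nodes_.nrow(), M = elems.nrow();
  mat nodes(nodes_.begin(), N, 3, false);
  mat disp(disp_.begin(), N, 3, false);
  mat matpar(matpar_.begin(), M, matpar_.ncol(), false);
  mat fiber(fiber_.begin(), M, 3, false);
  mat stressV(M, 6), strainV(M, 6);
  vec sP1(M), eP1(M), Jv(M), vol(M);
  vec Nsh; mat dN;
  mat Xe(8, 3), ue(8, 3);
  bool ok = true;
  for (int e = 0; e < M; ++e) {
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      Xe.row(a) = nodes.row(n);
      ue.row(a) = disp.row(n);
    }
    shape_hex(0.0, 0.0, 0.0, Nsh, dN);
    mat J0 = Xe.t() * dN;
    double detJ0 = det(J0);
    vol[e] = 8.0 * detJ0;
    if (detJ0 <= 0) { ok = false; stressV.row(e).zeros(); strainV.row(e).zeros();
      sP1[e] = eP1[e] = Jv[e] = datum::nan; continue; }
    mat dNdX = dN * inv(J0);
    mat F = eye(3, 3) + ue.t() * dNdX;
    double J = det(F);
    Jv[e] = J;
    mat C = F.t() * F;
    mat E = 0.5 * (C - eye(3, 3));
    rowvec mp = matpar.row(e);
    vec nf = fiber.row(e).t();
    double I1 = trace(C);
    double I4 = as_scalar(nf.t() * C * nf);
    MatPt d = mr_derivs(mp, I1, I4);
    mat S = 2.0 * d.W1 * eye(3, 3) + 2.0 * d.W2 * (I1 * eye(3, 3) - C)
      + 2.0 * d.W4 * (nf * nf.t());
    double p0 = 2.0 * (mp[0] + mp[2] * mp[3]) + 4.0 * mp[1];
    if (J > 0)
      S += (mp[6] * (J - 1.0) * J - p0) * inv_sympd(0.5 * (C + C.t()));
    mat sig = (F * S * F.t()) / J;
    stressV.row(e) = rowvec({sig(0,0), sig(1,1), sig(2,2),
                             sig(0,1), sig(1,2), sig(0,2)});
    strainV.row(e) = rowvec({E(0,0), E(1,1), E(2,2), E(0,1), E(1,2), E(0,2)});
    vec ev;
    eig_sym(ev, 0.5 * (sig + sig.t()));
    sP1[e] = ev.max();
    eig_sym(ev, E);
    eP1[e] = ev.max();
  }
  return List::create(
    _["ok"] = ok, _["stress"] = wrap(stressV), _["strain"] = wrap(strainV),
    _["stress_p1"] = NumericVector(sP1.begin(), sP1.end()),
    _["strain_p1"] = NumericVector(eP1.begin(), eP1.end()),
    _["J"] = NumericVector(Jv.begin(), Jv.end()),
    _["ref_volume"] = NumericVector(vol.begin(), vol.end()));
}

// [[Rcpp::export]]
NumericVector element_min_detj(NumericMatrix nodes_, IntegerMatrix elems) {
  int M = elems.nrow();
  mat nodes(nodes_.begin(), nodes_.nrow(), 3, false);
  NumericVector out(M);
  vec Nsh; mat dN;
  mat Xe(8, 3);
  for (int e = 0; e < M; ++e) {
    for (int a = 0; a < 8; ++a) Xe.row(a) = nodes.row(elems(e, a) - 1);
    double mn = datum::inf;
    for (int g = 0; g < 8; ++g) {
      double xi = (g & 1 ? GP : -GP);
      double eta = (g & 2 ? GP : -GP);
      double zeta = (g & 4 ? GP : -GP);
      shape_hex(xi, eta, zeta, Nsh, dN);
      mn = std::min(mn, det(Xe.t() * dN));
    }
    out[e] = mn;
  }
  return out;
}
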