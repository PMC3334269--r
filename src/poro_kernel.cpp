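// Finite-strain poroelastic kernels: constitutive law, element residuals of
// the equilibrium + volume-constraint system, follower-pressure facets, and
// kinematic summaries. Element tangents are obtained by central finite
// differences of the analytic element residual.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Params {
  double a, D1, D2, D3, rho_f;
  vec Q1, Q2, Q3;
};

static Params parse_params(const Rcpp::List& p) {
  Params P;
  P.a = Rcpp::as<double>(p["a"]);
  P.D1 = Rcpp::as<double>(p["D1"]);
  P.D2 = Rcpp::as<double>(p["D2"]);
  P.D3 = Rcpp::as<double>(p["D3"]);
  P.rho_f = Rcpp::as<double>(p["rho_f"]);
  P.Q1 = Rcpp::as<vec>(p["Q1"]);
  P.Q2 = Rcpp::as<vec>(p["Q2"]);
  P.Q3 = Rcpp::as<vec>(p["Q3"]);
  return P;
}

struct Kin {
  mat33 C, Cinv;
  double J, I1, I2, I1b, I2b;
};

static Kin kinematics(const mat33& F) {
  Kin k;
  k.J = det(F);
  if (!(k.J > 0)) Rcpp::stop("inverted element: J <= 0");
  k.C = F.t() * F;
  k.Cinv = inv_sympd(symmatu(k.C));
  k.I1 = trace(k.C);
  k.I2 = 0.5 * (k.I1 * k.I1 - trace(k.C * k.C));
  k.I1b = std::pow(k.J, -2.0 / 3.0) * k.I1;
  k.I2b = std::pow(k.J, -4.0 / 3.0) * k.I2;
  return k;
}

// exponent W and the mass sums s1,s2,s3
static double exponent_W(const Kin& k, const vec& m, const Params& P,
                         double& s1, double& s2, double& s3) {
  s1 = dot(P.Q1, m) / P.rho_f;
  s2 = dot(P.Q2, m) / P.rho_f;
  s3 = dot(P.Q3, m) / P.rho_f;
  return P.D1 * (k.I1b * (1.0 + s1) - 3.0) +
         P.D2 * (k.I2b * (1.0 + s2) - 3.0) +
         P.D3 * ((k.J - 1.0) * (k.J - 1.0) + s3 * s3);
}

static double psi_impl(const mat33& F, const vec& m, const Params& P) {
  Kin k = kinematics(F);
  double s1, s2, s3;
  double W = exponent_W(k, m, P, s1, s2, s3);
  return P.a * (std::exp(W) - 1.0);
}

// constitutive part of the second Piola-Kirchhoff stress, dPsi/dE
static mat33 pk2_con(const mat33& F, const vec& m, const Params& P,
                     const Kin& k) {
  double s1, s2, s3;
  double W = exponent_W(k, m, P, s1, s2, s3);
  mat33 I(fill::eye);
  mat33 dI1b = std::pow(k.J, -2.0 / 3.0) * (I - (k.I1 / 3.0) * k.Cinv);
  mat33 dI2b = std::pow(k.J, -4.0 / 3.0) *
               (k.I1 * I - k.C - (2.0 * k.I2 / 3.0) * k.Cinv);
  mat33 dJ = 0.5 * k.J * k.Cinv;
  mat33 dWdC = P.D1 * (1.0 + s1) * dI1b + P.D2 * (1.0 + s2) * dI2b +
               2.0 * P.D3 * (k.J - 1.0) * dJ;
  return 2.0 * P.a * std::exp(W) * dWdC;  // dPsi/dE = 2 dPsi/dC
}

static mat33 pk2_total(const mat33& F, const vec& m, double lambda,
                       const Params& P) {
  Kin k = kinematics(F);
  return pk2_con(F, m, P, k) + lambda * k.J * k.Cinv;
}

static vec dpsi_dm_impl(const mat33& F, const vec& m, const Params& P) {
  Kin k = kinematics(F);
  double s1, s2, s3;
  double W = exponent_W(k, m, P, s1, s2, s3);
  vec G = (P.D1 * k.I1b) * P.Q1 + (P.D2 * k.I2b) * P.Q2 +
          (2.0 * P.D3 * s3) * P.Q3;
  return P.a * std::exp(W) * G / P.rho_f;
}

// [[Rcpp::export]]
double cpp_strain_energy(const arma::mat& F, const arma::vec& m,
                         const Rcpp::List& params) {
  return psi_impl(mat33(F), m, parse_params(params));
}

// [[Rcpp::export]]
arma::mat cpp_pk2(const arma::mat& F, const arma::vec& m, double lambda,
                  const Rcpp::List& params) {
  return pk2_total(mat33(F), m, lambda, parse_params(params));
}

// [[Rcpp::export]]
arma::mat cpp_pk2_constitutive(const arma::mat& F, const arma::vec& m,
                               const Rcpp::List& params) {
  Params P = parse_params(params);
  mat33 Fm(F);
  Kin k = kinematics(Fm);
  return pk2_con(Fm, m, P, k);
}

// [[Rcpp::export]]
arma::vec cpp_dpsi_dm(const arma::mat& F, const arma::vec& m,
                      const Rcpp::List& params) {
  return dpsi_dm_impl(mat33(F), m, parse_params(params));
}

// P2 tetrahedral basis (4 vertices, 6 edges 12,13,14,23,24,34)
static void p2_basis(const vec4& L, vec& N, mat& dNdL) {
  static const int EA[6] = {0, 0, 0, 1, 1, 2};
  static const int EB[6] = {1, 2, 3, 2, 3, 3};
  N.set_size(10);
  dNdL.zeros(10, 4);
  for (int a = 0; a < 4; ++a) {
    N(a) = L(a) * (2.0 * L(a) - 1.0);
    dNdL(a, a) = 4.0 * L(a) - 1.0;
  }
  for (int e = 0; e < 6; ++e) {
    N(4 + e) = 4.0 * L(EA[e]) * L(EB[e]);
    dNdL(4 + e, EA[e]) = 4.0 * L(EB[e]);
    dNdL(4 + e, EB[e]) = 4.0 * L(EA[e]);
  }
}

struct ElemGeom {
  mat gradL;   // 4 x 3
  double vol6; // 6 * volume
};

static ElemGeom elem_geom(const mat& nodes, const ivec& vidx) {
  mat44 A;
  for (int a = 0; a < 4; ++a) {
    A(a, 0) = 1.0;
    for (int d = 0; d < 3; ++d) A(a, d + 1) = nodes(vidx(a), d);
  }
  ElemGeom g;
  g.vol6 = det(A);
  mat44 Ci = inv(A);
  g.gradL = Ci.rows(1, 3).t();  // 4 x 3
  return g;
}

// residual of one element: 30 displacement dofs then 4 multiplier dofs
static void elem_residual(const mat& Ye, const vec4& le, const mat& Me,
                          const std::vector<mat>& gradN,
                          const std::vector<vec>& Nq,
                          const std::vector<vec4>& Lq, const vec& qw,
                          double vol6, const Params& P, vec& out) {
  out.zeros(34);
  int nq = qw.n_elem;
  int N = Me.n_cols;
  for (int q = 0; q < nq; ++q) {
    const mat& gN = gradN[q];              // 10 x 3
    mat33 grady = Ye.t() * gN;             // (3x10)(10x3)
    mat33 F = grady + eye(3, 3);
    vec mq(N);
    for (int k = 0; k < N; ++k) mq(k) = dot(Me.col(k), Lq[q]);
    double lq = dot(le, Lq[q]);
    double J = det(F);
    if (!(J > 0)) Rcpp::stop("inverted element: J <= 0");
    mat33 S = pk2_total(F, mq, lq, P);
    mat PK1 = F * S;                        // 3 x 3
    mat cont = PK1 * gN.t();                // 3 x 10
    double w = qw(q) * vol6;
    for (int a = 0; a < 10; ++a)
      for (int i = 0; i < 3; ++i) out(3 * a + i) += w * cont(i, a);
    double c = J - 1.0 - accu(mq) / P.rho_f;
    for (int b = 0; b < 4; ++b) out(30 + b) += w * c * Lq[q](b);
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_assemble_solid(const arma::mat& nodes, const arma::imat& elems,
                              const arma::imat& conn, const arma::mat& y,
                              const arma::vec& lambda, const arma::mat& mmat,
                              const Rcpp::List& params,
                              const arma::mat& qbary, const arma::vec& qw,
                              bool want_jacobian, double fd_h = 1e-6) {
  Params P = parse_params(params);
  int mE = elems.n_rows, n2 = y.n_rows, nv = lambda.n_elem;
  int nq = qw.n_elem;
  int N = mmat.n_cols;
  // basis tables at quadrature points
  std::vector<vec> Nq(nq);
  std::vector<mat> dNdLq(nq);
  std::vector<vec4> Lq(nq);
  for (int q = 0; q < nq; ++q) {
    vec4 L;
    for (int a = 0; a < 4; ++a) L(a) = qbary(q, a);
    Lq[q] = L;
    p2_basis(L, Nq[q], dNdLq[q]);
  }
  vec R(3 * n2 + nv, fill::zeros);
  std::vector<double> ti, tj, tx;
  if (want_jacobian) {
    ti.reserve((size_t)mE * 34 * 34);
    tj.reserve((size_t)mE * 34 * 34);
    tx.reserve((size_t)mE * 34 * 34);
  }
  vec re(34), rp(34), rm(34);
  for (int e = 0; e < mE; ++e) {
    ivec vidx(4), didx(10);
    for (int a = 0; a < 4; ++a) vidx(a) = elems(e, a) - 1;
    for (int a = 0; a < 10; ++a) didx(a) = conn(e, a) - 1;
    ElemGeom g = elem_geom(nodes, vidx);
    std::vector<mat> gradN(nq);
    for (int q = 0; q < nq; ++q) gradN[q] = dNdLq[q] * g.gradL;  // 10x3
    mat Ye(10, 3);
    for (int a = 0; a < 10; ++a)
      for (int d = 0; d < 3; ++d) Ye(a, d) = y(didx(a), d);
    vec4 le;
    for (int b = 0; b < 4; ++b) le(b) = lambda(vidx(b));
    mat Me(4, N);
    for (int b = 0; b < 4; ++b)
      for (int k = 0; k < N; ++k) Me(b, k) = mmat(vidx(b), k);
    elem_residual(Ye, le, Me, gradN, Nq, Lq, qw, g.vol6, P, re);
    // scatter residual; global dofs: 3*(node-1)+i for y, 3*n2 + vnode for λ
    uvec gd(34);
    for (int a = 0; a < 10; ++a)
      for (int i = 0; i < 3; ++i) gd(3 * a + i) = 3 * didx(a) + i;
    for (int b = 0; b < 4; ++b) gd(30 + b) = 3 * n2 + vidx(b);
    for (int r = 0; r < 34; ++r) R(gd(r)) += re(r);
    if (!want_jacobian) continue;
    mat Ke(34, 34);
    for (int c = 0; c < 34; ++c) {
      mat Yp = Ye, Ym = Ye;
      vec4 lp = le, lm = le;
      double base = (c < 30) ? Ye(c / 3, c % 3) : le(c - 30);
      double h = fd_h * (1.0 + std::abs(base));
      if (c < 30) { Yp(c / 3, c % 3) += h; Ym(c / 3, c % 3) -= h; }
      else { lp(c - 30) += h; lm(c - 30) -= h; }
      elem_residual(Yp, lp, Me, gradN, Nq, Lq, qw, g.vol6, P, rp);
      elem_residual(Ym, lm, Me, gradN, Nq, Lq, qw, g.vol6, P, rm);
      vec col = (rp - rm) / (2.0 * h);
      for (int r = 0; r < 34; ++r) {
        if (col(r) != 0.0) {
          ti.push_back((double)(gd(r) + 1));
          tj.push_back((double)(gd(c) + 1));
          tx.push_back(col(r));
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("res") = R,
                            Rcpp::Named("i") = ti, Rcpp::Named("j") = tj,
                            Rcpp::Named("x") = tx);
}

// P2 triangle basis: vertices then edges (1,2),(1,3),(2,3)
static void p2_tri_basis(double xi, double eta, vec& N, mat& dN) {
  vec3 L = {1.0 - xi - eta, xi, eta};
  mat dL = {{-1.0, -1.0}, {1.0, 0.0}, {0.0, 1.0}};  // 3 x 2
  static const int EA[3] = {0, 0, 1};
  static const int EB[3] = {1, 2, 2};
  N.set_size(6);
  dN.zeros(6, 2);
  for (int a = 0; a < 3; ++a) {
    N(a) = L(a) * (2.0 * L(a) - 1.0);
    dN.row(a) = (4.0 * L(a) - 1.0) * dL.row(a);
  }
  for (int e = 0; e < 3; ++e) {
    N(3 + e) = 4.0 * L(EA[e]) * L(EB[e]);
    dN.row(3 + e) = 4.0 * (L(EA[e]) * dL.row(EB[e]) + L(EB[e]) * dL.row(EA[e]));
  }
}

// residual of follower pressure on one P2 facet (18 dofs)
static void facet_residual(const mat& Xf, const mat& Yf, double pres,
                           const std::vector<vec>& Nq,
                           const std::vector<mat>& dNq, const vec& qw,
                           vec& out) {
  out.zeros(18);
  int nq = qw.n_elem;
  for (int q = 0; q < nq; ++q) {
    mat xc = Xf + Yf;                       // 6 x 3 deformed facet nodes
    vec3 xs = (xc.t() * dNq[q].col(0));     // x_,xi
    vec3 xt = (xc.t() * dNq[q].col(1));     // x_,eta
    vec3 nvec = cross(xs, xt);              // outward * dA scaling
    for (int a = 0; a < 6; ++a)
      for (int i = 0; i < 3; ++i)
        out(3 * a + i) += pres * qw(q) * Nq[q](a) * nvec(i);
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_assemble_follower(const arma::mat& fcoords,
                                 const arma::imat& fconn, const arma::mat& y,
                                 double pressure, const arma::mat& qxi,
                                 const arma::vec& qw, bool want_jacobian,
                                 int n_y_dofs, double fd_h = 1e-6) {
  int nf = fconn.n_rows, nq = qw.n_elem;
  std::vector<vec> Nq(nq);
  std::vector<mat> dNq(nq);
  for (int q = 0; q < nq; ++q) p2_tri_basis(qxi(q, 0), qxi(q, 1), Nq[q], dNq[q]);
  vec R(n_y_dofs, fill::zeros);
  std::vector<double> ti, tj, tx;
  vec re(18), rp(18), rm(18);
  for (int f = 0; f < nf; ++f) {
    mat Xf(6, 3), Yf(6, 3);
    ivec didx(6);
    for (int a = 0; a < 6; ++a) {
      didx(a) = fconn(f, a) - 1;
      for (int d = 0; d < 3; ++d) {
        Xf(a, d) = fcoords(f, 3 * a + d);
        Yf(a, d) = y(didx(a), d);
      }
    }
    facet_residual(Xf, Yf, pressure, Nq, dNq, qw, re);
    uvec gd(18);
    for (int a = 0; a < 6; ++a)
      for (int i = 0; i < 3; ++i) gd(3 * a + i) = 3 * didx(a) + i;
    for (int r = 0; r < 18; ++r) R(gd(r)) += re(r);
    if (!want_jacobian) continue;
    for (int c = 0; c < 18; ++c) {
      mat Yp = Yf, Ym = Yf;
      double h = fd_h * (1.0 + std::abs(Yf(c / 3, c % 3)));
      Yp(c / 3, c % 3) += h;
      Ym(c / 3, c % 3) -= h;
      facet_residual(Xf, Yp, pressure, Nq, dNq, qw, rp);
      facet_residual(Xf, Ym, pressure, Nq, dNq, qw, rm);
      vec col = (rp - rm) / (2.0 * h);
      for (int r = 0; r < 18; ++r) {
        if (col(r) != 0.0) {
          ti.push_back((double)(gd(r) + 1));
          tj.push_back((double)(gd(c) + 1));
          tx.push_back(col(r));
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("res") = R,
                            Rcpp::Named("i") = ti, Rcpp::Named("j") = tj,
                            Rcpp::Named("x") = tx);
}

// per-element deformation summaries at the barycentre
// [[Rcpp::export]]
Rcpp::List cpp_elem_kinematics(const arma::mat& nodes, const arma::imat& elems,
                               const arma::imat& conn, const arma::mat& y) {
  int mE = elems.n_rows;
  vec4 L = {0.25, 0.25, 0.25, 0.25};
  vec N;
  mat dNdL;
  p2_basis(L, N, dNdL);
  mat Fout(mE, 9);
  vec Jv(mE), I1b(mE), I2b(mE);
  for (int e = 0; e < mE; ++e) {
    ivec vidx(4);
    for (int a = 0; a < 4; ++a) vidx(a) = elems(e, a) - 1;
    ElemGeom g = elem_geom(nodes, vidx);
    mat gN = dNdL * g.gradL;
    mat Ye(10, 3);
    for (int a = 0; a < 10; ++a)
      for (int d = 0; d < 3; ++d) Ye(a, d) = y(conn(e, a) - 1, d);
    mat33 F = mat33(Ye.t() * gN) + eye(3, 3);
    Kin k = kinematics(F);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) Fout(e, 3 * j + i) = F(i, j);  // col-major
    Jv(e) = k.J;
    I1b(e) = k.I1b;
    I2b(e) = k.I2b;
  }
  return Rcpp::List::create(Rcpp::Named("F") = Fout, Rcpp::Named("J") = Jv,
                            Rcpp::Named("I1b") = I1b,
                            Rcpp::Named("I2b") = I2b);
}

// integral of J over the reference domain (deformed volume)
// [[Rcpp::export]]
double cpp_deformed_volume(const arma::mat& nodes, const arma::imat& elems,
                           const arma::imat& conn, const arma::mat& y,
                           const arma::mat& qbary, const arma::vec& qw) {
  int mE = elems.n_rows, nq = qw.n_elem;
  std::vector<vec> Nq(nq);
  std::vector<mat> dNdLq(nq);
  std::vector<vec4> Lq(nq);
  for (int q = 0; q < nq; ++q) {
    vec4 L;
    for (int a = 0; a < 4; ++a) L(a) = qbary(q, a);
    Lq[q] = L;
    p2_basis(L, Nq[q], dNdLq[q]);
  }
  double total = 0.0;
  for (int e = 0; e < mE; ++e) {
    ivec vidx(4);
    for (int a = 0; a < 4; ++a) vidx(a) = elems(e, a) - 1;
    ElemGeom g = elem_geom(nodes, vidx);
    mat Ye(10, 3);
    for (int a = 0; a < 10; ++a)
      for (int d = 0; d < 3; ++d) Ye(a, d) = y(conn(e, a) - 1, d);
    for (int q = 0; q < nq; ++q) {
      mat gN = dNdLq[q] * g.gradL;
      mat33 F = mat33(Ye.t() * gN) + eye(3, 3);
      total += qw(q) * g.vol6 * det(F);
    }
  }
  return total;
}
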