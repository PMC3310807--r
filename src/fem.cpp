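// Quadratic-triangle (T6) plane elasticity kernels: stiffness assembly,
// constitutive rotation and Gauss-point stress recovery. Units are mm / kPa;
// element thickness is unity.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// 3-point Gauss rule on the reference triangle (degree-2 exact)
static const double GP[3][2] = {
  {1.0 / 6.0, 1.0 / 6.0},
  {2.0 / 3.0, 1.0 / 6.0},
  {1.0 / 6.0, 2.0 / 3.0}
};
static const double GW = 1.0 / 6.0;

// Shape functions and parametric derivatives for the 6-node triangle.
// Node order: corners 1-3 (CCW), midsides 4 (1-2), 5 (2-3), 6 (3-1).
static void t6_shape(double xi, double eta, vec &N, mat &dN) {
  const double L1 = 1.0 - xi - eta, L2 = xi, L3 = eta;
  N.set_size(6);
  N(0) = L1 * (2.0 * L1 - 1.0);
  N(1) = L2 * (2.0 * L2 - 1.0);
  N(2) = L3 * (2.0 * L3 - 1.0);
  N(3) = 4.0 * L1 * L2;
  N(4) = 4.0 * L2 * L3;
  N(5) = 4.0 * L3 * L1;
  dN.set_size(6, 2);
  // d/dxi                         d/deta
  dN(0, 0) = 1.0 - 4.0 * L1;       dN(0, 1) = 1.0 - 4.0 * L1;
  dN(1, 0) = 4.0 * L2 - 1.0;       dN(1, 1) = 0.0;
  dN(2, 0) = 0.0;                  dN(2, 1) = 4.0 * L3 - 1.0;
  dN(3, 0) = 4.0 * (L1 - L2);      dN(3, 1) = -4.0 * L2;
  dN(4, 0) = 4.0 * L3;             dN(4, 1) = 4.0 * L2;
  dN(5, 0) = -4.0 * L3;            dN(5, 1) = 4.0 * (L1 - L3);
}

// Engineering-strain transformation global -> local for a rotation by phi.
static mat strain_rotation(double phi) {
  const double c = std::cos(phi), s = std::sin(phi);
  mat T(3, 3);
  T(0, 0) = c * c;       T(0, 1) = s * s;      T(0, 2) = c * s;
  T(1, 0) = s * s;       T(1, 1) = c * c;      T(1, 2) = -c * s;
  T(2, 0) = -2.0 * c * s; T(2, 1) = 2.0 * c * s; T(2, 2) = c * c - s * s;
  return T;
}

// Rotate per-element local stiffness matrices (rows of Dloc, column-major
// 3x3) into global axes: D_g = T^T D_l T.
// [[Rcpp::export]]
arma::mat fem_rotate_D(const arma::mat &Dloc, const arma::vec &phi) {
  const uword m = Dloc.n_rows;
  mat out(m, 9);
  for (uword e = 0; e < m; ++e) {
    mat Dl = reshape(Dloc.row(e).t(), 3, 3);
    mat T = strain_rotation(phi(e));
    mat Dg = T.t() * Dl * T;
    out.row(e) = vectorise(Dg).t();
  }
  return out;
}

// Assemble element stiffness contributions as COO triplets.
// nodes: n x 2, elems: m x 6 (1-based), Dg: m x 9 (global 3x3, column-major).
// [[Rcpp::export]]
Rcpp::List fem_assemble(const arma::mat &nodes, const arma::imat &elems,
                        const arma::mat &Dg) {
  const uword m = elems.n_rows;
  Rcpp::IntegerVector ti(144 * m), tj(144 * m);
  Rcpp::NumericVector tx(144 * m);
  vec N;
  mat dN;
  uword pos = 0;
  for (uword e = 0; e < m; ++e) {
    mat coords(6, 2);
    uvec dof(12);
    for (uword a = 0; a < 6; ++a) {
      const uword n = (uword)elems(e, a) - 1;
      coords(a, 0) = nodes(n, 0);
      coords(a, 1) = nodes(n, 1);
      dof(2 * a) = 2 * n;       // 0-based ux
      dof(2 * a + 1) = 2 * n + 1;
    }
    mat D = reshape(Dg.row(e).t(), 3, 3);
    mat Ke(12, 12, fill::zeros);
    for (int g = 0; g < 3; ++g) {
      t6_shape(GP[g][0], GP[g][1], N, dN);
      mat Jm = coords.t() * dN;        // (2x6)(6x2): J(a,b) = dx_a/dxi_b
      const double detJ = det(Jm);
      if (detJ <= 0.0)
        Rcpp::stop("non-positive Jacobian in element %d", (int)e + 1);
      mat dNxy = dN * inv(Jm);         // dN_i/dx_a
      mat B(3, 12, fill::zeros);
      for (uword a = 0; a < 6; ++a) {
        B(0, 2 * a) = dNxy(a, 0);
        B(1, 2 * a + 1) = dNxy(a, 1);
        B(2, 2 * a) = dNxy(a, 1);
        B(2, 2 * a + 1) = dNxy(a, 0);
      }
      Ke += (GW * detJ) * (B.t() * D * B);
    }
    for (uword a = 0; a < 12; ++a)
      for (uword b = 0; b < 12; ++b) {
        ti[pos] = (int)dof(a) + 1;   // back to 1-based for R
        tj[pos] = (int)dof(b) + 1;
        tx[pos] = Ke(a, b);
        ++pos;
      }
  }
  return Rcpp::List::create(Rcpp::Named("i") = ti, Rcpp::Named("j") = tj,
                            Rcpp::Named("x") = tx);
}

// Recover stresses and strains at the 3 Gauss points of every element.
// u: 2n displacement vector (ux1, uy1, ...). Returns per element the
// Gauss-point stress components (sxx, syy, sxy) x 3, strain components x 3
// and Gauss-point coordinates (x, y) x 3.
// [[Rcpp::export]]
Rcpp::List fem_stress(const arma::mat &nodes, const arma::imat &elems,
                      const arma::mat &Dg, const arma::vec &u) {
  const uword m = elems.n_rows;
  mat stress(m, 9), strain(m, 9), gpxy(m, 6);
  vec N;
  mat dN;
  for (uword e = 0; e < m; ++e) {
    mat coords(6, 2);
    vec ue(12);
    for (uword a = 0; a < 6; ++a) {
      const uword n = (uword)elems(e, a) - 1;
      coords(a, 0) = nodes(n, 0);
      coords(a, 1) = nodes(n, 1);
      ue(2 * a) = u(2 * n);
      ue(2 * a + 1) = u(2 * n + 1);
    }
    mat D = reshape(Dg.row(e).t(), 3, 3);
    for (int g = 0; g < 3; ++g) {
      t6_shape(GP[g][0], GP[g][1], N, dN);
      mat Jm = coords.t() * dN;
      mat dNxy = dN * inv(Jm);
      vec eps(3, fill::zeros);
      double gx = 0.0, gy = 0.0;
      for (uword a = 0; a < 6; ++a) {
        eps(0) += dNxy(a, 0) * ue(2 * a);
        eps(1) += dNxy(a, 1) * ue(2 * a + 1);
        eps(2) += dNxy(a, 1) * ue(2 * a) + dNxy(a, 0) * ue(2 * a + 1);
        gx += N(a) * coords(a, 0);
        gy += N(a) * coords(a, 1);
      }
      vec sig = D * eps;
      for (int k = 0; k < 3; ++k) {
        stress(e, 3 * g + k) = sig(k);
        strain(e, 3 * g + k) = eps(k);
      }
      gpxy(e, 2 * g) = gx;
      gpxy(e, 2 * g + 1) = gy;
    }
  }
  return Rcpp::List::create(Rcpp::Named("stress") = stress,
                            Rcpp::Named("strain") = strain,
                            Rcpp::Named("gp_xy") = gpxy);
}
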