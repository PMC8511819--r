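// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Linear-elastic tetrahedral FE kernels. Units: mm, N, MPa. Voigt order
// (xx, yy, zz, xy, yz, xz) with engineering shear strains (gamma = 2*eps).
// TET10 elements are subparametric with straight edges: the geometry map uses
// the 4 corner nodes (constant Jacobian), the field is quadratic; 4-point
// Gauss integration is then exact for the stiffness integrand.

static const int EDGES[6][2] = {{0,1},{1,2},{0,2},{0,3},{1,3},{2,3}};

static arma::mat66 dmatrix(double E, double nu) {
  const double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  const double mu = E / (2.0 * (1.0 + nu));
  arma::mat66 D(arma::fill::zeros);
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) D(i, j) = lam;
    D(i, i) = lam + 2.0 * mu;
    D(i + 3, i + 3) = mu;
  }
  return D;
}

// gradients (rows) of the 4 barycentric coordinates w.r.t. x, given Jinv
static arma::mat gradL(const arma::mat33 &Jinv) {
  arma::mat G(4, 3);
  G.row(1) = Jinv.row(0);
  G.row(2) = Jinv.row(1);
  G.row(3) = Jinv.row(2);
  G.row(0) = -(G.row(1) + G.row(2) + G.row(3));
  return G;
}

static void bmatrix(const arma::mat &gradN, arma::mat &B) {
  const int nn = gradN.n_rows;
  B.zeros(6, 3 * nn);
  for (int i = 0; i < nn; ++i) {
    const double gx = gradN(i, 0), gy = gradN(i, 1), gz = gradN(i, 2);
    B(0, 3 * i) = gx;
    B(1, 3 * i + 1) = gy;
    B(2, 3 * i + 2) = gz;
    B(3, 3 * i) = gy; B(3, 3 * i + 1) = gx;
    B(4, 3 * i + 1) = gz; B(4, 3 * i + 2) = gy;
    B(5, 3 * i) = gz; B(5, 3 * i + 2) = gx;
  }
}

// quadratic shape-function gradients at barycentric point L (length 4)
static arma::mat gradN10(const arma::vec4 &L, const arma::mat &GL) {
  arma::mat G(10, 3);
  for (int c = 0; c < 4; ++c) G.row(c) = (4.0 * L(c) - 1.0) * GL.row(c);
  for (int e = 0; e < 6; ++e) {
    const int a = EDGES[e][0], b = EDGES[e][1];
    G.row(4 + e) = 4.0 * (L(a) * GL.row(b) + L(b) * GL.row(a));
  }
  return G;
}

static const double GA = 0.5854101966249685, GB = 0.1381966011250105;

static void gauss_points(arma::mat &P) {
  P.set_size(4, 4);  // rows: points, cols: L0..L3
  P.fill(GB);
  for (int i = 0; i < 4; ++i) P(i, i) = GA;
}

struct ElemGeom {
  arma::mat33 Jinv;
  double vol;
};

static ElemGeom elem_geom(const NumericMatrix &nodes, const IntegerMatrix &elems,
                          int e) {
  arma::mat33 J;
  const int n0 = elems(e, 0) - 1;
  for (int c = 0; c < 3; ++c) {
    const int nc = elems(e, c + 1) - 1;
    for (int k = 0; k < 3; ++k) J(k, c) = nodes(nc, k) - nodes(n0, k);
  }
  const double detJ = arma::det(J);
  if (detJ <= 0.0)
    stop("inverted element (non-positive Jacobian) at element %d", e + 1);
  ElemGeom g;
  g.Jinv = arma::inv(J);
  g.vol = detJ / 6.0;
  return g;
}

// [[Rcpp::export]]
List cpp_assemble(NumericMatrix nodes, IntegerMatrix elems, NumericVector E,
                  NumericVector nu, int order) {
  const int ne = elems.nrow();
  const int npe = (order == 2) ? 10 : 4;
  const int ndpe = 3 * npe;
  const size_t ntrip = (size_t)ne * ndpe * ndpe;

  IntegerVector ti(ntrip), tj(ntrip);
  NumericVector tx(ntrip);

  arma::mat P;
  gauss_points(P);
  arma::mat B, Ke;

  size_t t = 0;
  for (int e = 0; e < ne; ++e) {
    const ElemGeom g = elem_geom(nodes, elems, e);
    const arma::mat66 D = dmatrix(E[e], nu[e]);
    const arma::mat GL = gradL(g.Jinv);
    if (order == 1) {
      bmatrix(GL, B);
      Ke = g.vol * B.t() * D * B;
    } else {
      Ke.zeros(30, 30);
      for (int q = 0; q < 4; ++q) {
        const arma::vec4 L = P.row(q).t();
        const arma::mat GN = gradN10(L, GL);
        bmatrix(GN, B);
        Ke += (g.vol / 4.0) * B.t() * D * B;
      }
    }
    int dof[30];
    for (int a = 0; a < npe; ++a) {
      const int n = elems(e, a) - 1;
      dof[3 * a] = 3 * n; dof[3 * a + 1] = 3 * n + 1; dof[3 * a + 2] = 3 * n + 2;
    }
    for (int a = 0; a < ndpe; ++a)
      for (int b = 0; b < ndpe; ++b, ++t) {
        ti[t] = dof[a] + 1;
        tj[t] = dof[b] + 1;
        tx[t] = Ke(a, b);
      }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx);
}

// Per-element strain and stress (Voigt, engineering shear), averaged over the
// integration points (constant for TET4). Columns 1:6 strain, 7:12 stress.
// [[Rcpp::export]]
NumericMatrix cpp_element_fields(NumericMatrix nodes, IntegerMatrix elems,
                                 NumericVector E, NumericVector nu,
                                 NumericVector u, int order) {
  const int ne = elems.nrow();
  const int npe = (order == 2) ? 10 : 4;
  NumericMatrix out(ne, 12);

  arma::mat P;
  gauss_points(P);
  arma::mat B;

  for (int e = 0; e < ne; ++e) {
    const ElemGeom g = elem_geom(nodes, elems, e);
    const arma::mat GL = gradL(g.Jinv);
    arma::vec ue(3 * npe);
    for (int a = 0; a < npe; ++a) {
      const int n = elems(e, a) - 1;
      for (int k = 0; k < 3; ++k) ue(3 * a + k) = u[3 * n + k];
    }
    arma::vec6 eps(arma::fill::zeros);
    if (order == 1) {
      bmatrix(GL, B);
      eps = B * ue;
    } else {
      for (int q = 0; q < 4; ++q) {
        const arma::vec4 L = P.row(q).t();
        const arma::mat GN = gradN10(L, GL);
        bmatrix(GN, B);
        eps += 0.25 * (B * ue);
      }
    }
    const arma::vec6 sig = dmatrix(E[e], nu[e]) * eps;
    for (int k = 0; k < 6; ++k) {
      out(e, k) = eps(k);
      out(e, k + 6) = sig(k);
    }
  }
  return out;
}
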