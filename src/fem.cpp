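// Element-level finite-element kernels for linear tetrahedra (tet4) and
// quadratic tetrahedra (tet10): stiffness triplets for isotropic linear
// elasticity and for an anisotropic Laplace (dielectric) operator, plus
// element stress recovery and a brute-force nearest-centroid matcher.
//
// Conventions: node/element indices arrive 1-based from R; triplets are
// returned 1-based. Voigt order for stress/strain: xx, yy, zz, xy, yz, zx
// with engineering shear strains. tet10 node order: 4 corners, then edge
// midpoints (1,2), (2,3), (1,3), (1,4), (2,4), (3,4).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// 4-point Gauss rule on the reference tetrahedron (degree 2), weights sum
// to the reference volume 1/6.
const double QA = 0.5854101966249685;
const double QB = 0.1381966011250105;
const double QW = 1.0 / 24.0;

void tet10_dshape(double xi, double eta, double zeta, arma::mat& dN) {
  // L1 = 1-xi-eta-zeta, L2 = xi, L3 = eta, L4 = zeta
  double L1 = 1.0 - xi - eta - zeta, L2 = xi, L3 = eta, L4 = zeta;
  // dL/d(xi,eta,zeta)
  const double dL[4][3] = {{-1, -1, -1}, {1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  const double L[4] = {L1, L2, L3, L4};
  dN.zeros(10, 3);
  for (int c = 0; c < 3; ++c) {
    for (int i = 0; i < 4; ++i) dN(i, c) = (4.0 * L[i] - 1.0) * dL[i][c];
    // edges in canonical order (1-based pairs): (1,2),(2,3),(1,3),(1,4),(2,4),(3,4)
    const int ea[6] = {0, 1, 0, 0, 1, 2};
    const int eb[6] = {1, 2, 2, 3, 3, 3};
    for (int e = 0; e < 6; ++e)
      dN(4 + e, c) = 4.0 * (dL[ea[e]][c] * L[eb[e]] + L[ea[e]] * dL[eb[e]][c]);
  }
}

// Jacobian with columns = d x / d xi_a for the straight-edge corner map.
// For tet10 we use the isoparametric map (all 10 nodes).
double shape_grads(const arma::mat& X, const arma::mat& dN, arma::mat& G) {
  arma::mat Jac = X.t() * dN;  // 3 x 3, X is (nn x 3), dN is (nn x 3)
  double detJ = arma::det(Jac);
  arma::mat Jinv = arma::inv(Jac);
  G = dN * Jinv;  // nn x 3 spatial gradients
  return detJ;
}

void dmatrix(double E, double nu, arma::mat& D) {
  double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  double mu = E / (2.0 * (1.0 + nu));
  D.zeros(6, 6);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) D(i, j) = lam;
  for (int i = 0; i < 3; ++i) D(i, i) = lam + 2.0 * mu;
  for (int i = 3; i < 6; ++i) D(i, i) = mu;
}

void bmatrix(const arma::mat& G, arma::mat& B) {
  int nn = G.n_rows;
  B.zeros(6, 3 * nn);
  for (int i = 0; i < nn; ++i) {
    double gx = G(i, 0), gy = G(i, 1), gz = G(i, 2);
    B(0, 3 * i + 0) = gx;
    B(1, 3 * i + 1) = gy;
    B(2, 3 * i + 2) = gz;
    B(3, 3 * i + 0) = gy; B(3, 3 * i + 1) = gx;
    B(4, 3 * i + 1) = gz; B(4, 3 * i + 2) = gy;
    B(5, 3 * i + 0) = gz; B(5, 3 * i + 2) = gx;
  }
}

void qpoints(std::vector<std::array<double, 3>>& qp) {
  qp = {{QA, QB, QB}, {QB, QA, QB}, {QB, QB, QA}, {QB, QB, QB}};
}

}  // namespace

// [[Rcpp::export]]
List fem_stiffness_elastic(const arma::mat& nodes, const arma::imat& tets,
                           const arma::vec& E, double nu) {
  const int m = tets.n_rows, nn = tets.n_cols;
  if (nn != 4 && nn != 10) stop("elements must be tet4 or tet10");
  const int nd = 3 * nn;
  const std::size_t per = (std::size_t)nd * nd;
  IntegerVector ti((std::size_t)m * per), tj((std::size_t)m * per);
  NumericVector tx((std::size_t)m * per);

  arma::mat dN4 = {{-1, -1, -1}, {1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  std::vector<std::array<double, 3>> qp;
  qpoints(qp);

  arma::mat X(nn, 3), G, B, D(6, 6), Ke(nd, nd), dN;
  std::size_t pos = 0;
  for (int e = 0; e < m; ++e) {
    for (int a = 0; a < nn; ++a) X.row(a) = nodes.row(tets(e, a) - 1);
    dmatrix(E[e], nu, D);
    Ke.zeros();
    if (nn == 4) {
      double detJ = shape_grads(X, dN4, G);
      if (detJ <= 0) stop("non-positive element Jacobian (element %d)", e + 1);
      bmatrix(G, B);
      Ke = B.t() * D * B * (detJ / 6.0);
    } else {
      for (auto& q : qp) {
        tet10_dshape(q[0], q[1], q[2], dN);
        double detJ = shape_grads(X, dN, G);
        if (detJ <= 0) stop("non-positive element Jacobian (element %d)", e + 1);
        bmatrix(G, B);
        Ke += B.t() * D * B * (detJ * QW);
      }
    }
    for (int a = 0; a < nn; ++a)
      for (int ca = 0; ca < 3; ++ca) {
        int gi = 3 * (tets(e, a) - 1) + ca + 1;
        int li = 3 * a + ca;
        for (int b = 0; b < nn; ++b)
          for (int cb = 0; cb < 3; ++cb) {
            ti[pos] = gi;
            tj[pos] = 3 * (tets(e, b) - 1) + cb + 1;
            tx[pos] = Ke(li, 3 * b + cb);
            ++pos;
          }
      }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx);
}

// [[Rcpp::export]]
arma::mat fem_element_stress(const arma::mat& nodes, const arma::imat& tets,
                             const arma::vec& E, double nu,
                             const arma::vec& U) {
  const int m = tets.n_rows, nn = tets.n_cols;
  arma::mat out(m, 6);
  arma::mat dN4 = {{-1, -1, -1}, {1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  std::vector<std::array<double, 3>> qp;
  qpoints(qp);
  arma::mat X(nn, 3), G, B, D(6, 6), dN;
  arma::vec ue(3 * nn), sig(6);
  for (int e = 0; e < m; ++e) {
    for (int a = 0; a < nn; ++a) {
      X.row(a) = nodes.row(tets(e, a) - 1);
      for (int c = 0; c < 3; ++c) ue[3 * a + c] = U[3 * (tets(e, a) - 1) + c];
    }
    dmatrix(E[e], nu, D);
    if (nn == 4) {
      shape_grads(X, dN4, G);
      bmatrix(G, B);
      sig = D * (B * ue);
    } else {
      sig.zeros();
      double vol = 0.0;
      for (auto& q : qp) {
        tet10_dshape(q[0], q[1], q[2], dN);
        double detJ = shape_grads(X, dN, G);
        bmatrix(G, B);
        sig += (D * (B * ue)) * (detJ * QW);
        vol += detJ * QW;
      }
      sig /= vol;  // volume-averaged over quadrature points
    }
    out.row(e) = sig.t();
  }
  return out;
}

// [[Rcpp::export]]
List fem_stiffness_laplace(const arma::mat& nodes, const arma::imat& tets,
                           const arma::mat& tensor, const arma::vec& scale) {
  const int m = tets.n_rows, nn = tets.n_cols;
  if (nn != 4 && nn != 10) stop("elements must be tet4 or tet10");
  const std::size_t per = (std::size_t)nn * nn;
  IntegerVector ti((std::size_t)m * per), tj((std::size_t)m * per);
  NumericVector tx((std::size_t)m * per);
  arma::mat dN4 = {{-1, -1, -1}, {1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  std::vector<std::array<double, 3>> qp;
  qpoints(qp);
  arma::mat X(nn, 3), G, Ke(nn, nn), dN;
  std::size_t pos = 0;
  for (int e = 0; e < m; ++e) {
    for (int a = 0; a < nn; ++a) X.row(a) = nodes.row(tets(e, a) - 1);
    arma::mat K3 = tensor * scale[e];
    Ke.zeros();
    if (nn == 4) {
      double detJ = shape_grads(X, dN4, G);
      if (detJ <= 0) stop("non-positive element Jacobian (element %d)", e + 1);
      Ke = G * K3 * G.t() * (detJ / 6.0);
    } else {
      for (auto& q : qp) {
        tet10_dshape(q[0], q[1], q[2], dN);
        double detJ = shape_grads(X, dN, G);
        if (detJ <= 0) stop("non-positive element Jacobian (element %d)", e + 1);
        Ke += G * K3 * G.t() * (detJ * QW);
      }
    }
    for (int a = 0; a < nn; ++a)
      for (int b = 0; b < nn; ++b) {
        ti[pos] = tets(e, a);
        tj[pos] = tets(e, b);
        tx[pos] = Ke(a, b);
        ++pos;
      }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx);
}

// [[Rcpp::export]]
NumericVector fem_tet_volumes(const arma::mat& nodes, const arma::imat& tets) {
  const int m = tets.n_rows;
  NumericVector v(m);
  for (int e = 0; e < m; ++e) {
    arma::rowvec a = nodes.row(tets(e, 0) - 1);
    arma::rowvec d1 = nodes.row(tets(e, 1) - 1) - a;
    arma::rowvec d2 = nodes.row(tets(e, 2) - 1) - a;
    arma::rowvec d3 = nodes.row(tets(e, 3) - 1) - a;
    v[e] = arma::det(arma::join_cols(d1, d2, d3)) / 6.0;
  }
  return v;
}

// Nearest neighbour of each query point among reference points, with an
// optional distance cap (cap <= 0 means uncapped). Returns 1-based index,
// 0 where no reference point lies within the cap.
// [[Rcpp::export]]
List nearest_points(const arma::mat& query, const arma::mat& ref, double cap) {
  const int nq = query.n_rows, nr = ref.n_rows;
  IntegerVector idx(nq);
  NumericVector dist(nq);
  double cap2 = cap > 0 ? cap * cap : arma::datum::inf;
  for (int i = 0; i < nq; ++i) {
    double best = arma::datum::inf;
    int bi = 0;
    for (int j = 0; j < nr; ++j) {
      double dx = query(i, 0) - ref(j, 0);
      double dy = query(i, 1) - ref(j, 1);
      double dz = query(i, 2) - ref(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = j + 1; }
    }
    if (best <= cap2) { idx[i] = bi; dist[i] = std::sqrt(best); }
    else { idx[i] = 0; dist[i] = NA_REAL; }
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Minimum distance from each query point to any of a set of points
// (used for surface-distance classification of elements).
// [[Rcpp::export]]
NumericVector min_distance_to(const arma::mat& query, const arma::mat& ref) {
  const int nq = query.n_rows, nr = ref.n_rows;
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = arma::datum::inf;
    for (int j = 0; j < nr; ++j) {
      double dx = query(i, 0) - ref(j, 0);
      double dy = query(i, 1) - ref(j, 1);
      double dz = query(i, 2) - ref(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
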