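// Compiled kernels for the hexahedral finite-element solver and for
// point-to-surface projection.  Voigt order throughout:
// (xx, yy, zz, yz, xz, xy) with engineering shear strains.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// local node coordinates of the serendipity hex (corners then mid-edges)
static const double XI20[20][3] = {
  {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
  {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1},
  {0, -1, -1},  {1, 0, -1},  {0, 1, -1}, {-1, 0, -1},
  {0, -1, 1},   {1, 0, 1},   {0, 1, 1},  {-1, 0, 1},
  {-1, -1, 0},  {1, -1, 0},  {1, 1, 0},  {-1, 1, 0}};

// shape-function derivatives w.r.t. local coords; returns nen x 3
static void shape_deriv(int nen, double xi, double eta, double ze,
                        arma::mat &dN) {
  dN.set_size(nen, 3);
  if (nen == 8) {
    for (int a = 0; a < 8; ++a) {
      double xa = XI20[a][0], ya = XI20[a][1], za = XI20[a][2];
      dN(a, 0) = 0.125 * xa * (1 + ya * eta) * (1 + za * ze);
      dN(a, 1) = 0.125 * (1 + xa * xi) * ya * (1 + za * ze);
      dN(a, 2) = 0.125 * (1 + xa * xi) * (1 + ya * eta) * za;
    }
  } else {
    for (int a = 0; a < 20; ++a) {
      double xa = XI20[a][0], ya = XI20[a][1], za = XI20[a][2];
      if (a < 8) {
        double s = xa * xi + ya * eta + za * ze;
        dN(a, 0) = 0.125 * xa * (1 + ya * eta) * (1 + za * ze) * (2 * xa * xi + ya * eta + za * ze - 1);
        dN(a, 1) = 0.125 * (1 + xa * xi) * ya * (1 + za * ze) * (xa * xi + 2 * ya * eta + za * ze - 1);
        dN(a, 2) = 0.125 * (1 + xa * xi) * (1 + ya * eta) * za * (xa * xi + ya * eta + 2 * za * ze - 1);
        (void)s;
      } else if (xa == 0) {
        dN(a, 0) = -0.5 * xi * (1 + ya * eta) * (1 + za * ze);
        dN(a, 1) = 0.25 * (1 - xi * xi) * ya * (1 + za * ze);
        dN(a, 2) = 0.25 * (1 - xi * xi) * (1 + ya * eta) * za;
      } else if (ya == 0) {
        dN(a, 0) = 0.25 * xa * (1 - eta * eta) * (1 + za * ze);
        dN(a, 1) = -0.5 * eta * (1 + xa * xi) * (1 + za * ze);
        dN(a, 2) = 0.25 * (1 + xa * xi) * (1 - eta * eta) * za;
      } else {
        dN(a, 0) = 0.25 * xa * (1 + ya * eta) * (1 - ze * ze);
        dN(a, 1) = 0.25 * (1 + xa * xi) * ya * (1 - ze * ze);
        dN(a, 2) = -0.5 * ze * (1 + xa * xi) * (1 + ya * eta);
      }
    }
  }
}

static void gauss_rule(int npt1d, std::vector<double> &pts,
                       std::vector<double> &wts) {
  if (npt1d == 2) {
    double g = 1.0 / std::sqrt(3.0);
    pts = {-g, g};
    wts = {1.0, 1.0};
  } else {
    double g = std::sqrt(3.0 / 5.0);
    pts = {-g, 0.0, g};
    wts = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};
  }
}

// B matrix (6 x 3*nen) from cartesian shape derivatives dNdx (nen x 3)
static void fill_B(const arma::mat &dNdx, arma::mat &B) {
  int nen = dNdx.n_rows;
  B.zeros(6, 3 * nen);
  for (int a = 0; a < nen; ++a) {
    double bx = dNdx(a, 0), by = dNdx(a, 1), bz = dNdx(a, 2);
    B(0, 3 * a) = bx;
    B(1, 3 * a + 1) = by;
    B(2, 3 * a + 2) = bz;
    B(3, 3 * a + 1) = bz; B(3, 3 * a + 2) = by;   // gamma_yz
    B(4, 3 * a) = bz;     B(4, 3 * a + 2) = bx;   // gamma_xz
    B(5, 3 * a) = by;     B(5, 3 * a + 1) = bx;   // gamma_xy
  }
}

struct GPCache {
  std::vector<arma::mat> dN;   // per gp: nen x 3 local derivatives
  std::vector<double> w;
};

static void build_cache(int nen, int npt1d, GPCache &c) {
  std::vector<double> p, w;
  gauss_rule(npt1d, p, w);
  c.dN.clear(); c.w.clear();
  for (size_t k = 0; k < p.size(); ++k)
    for (size_t j = 0; j < p.size(); ++j)
      for (size_t i = 0; i < p.size(); ++i) {
        arma::mat d;
        shape_deriv(nen, p[i], p[j], p[k], d);
        c.dN.push_back(d);
        c.w.push_back(w[i] * w[j] * w[k]);
      }
}

// element-wise cartesian derivative computation; returns detJ
static double cart_deriv(const arma::mat &coords, const arma::mat &dN,
                         arma::mat &dNdx) {
  arma::mat J = dN.t() * coords;          // J(r, c) = dx_c / dxi_r
  double detJ = arma::det(J);
  dNdx = dN * arma::inv(J).t();           // chain rule: dN/dx = dN/dxi inv(J)^T
  return detJ;
}

// [[Rcpp::export]]
arma::mat cpp_hex_stiffness(const arma::mat &nodes, const arma::imat &conn,
                            const arma::mat &Dmat, bool bbar) {
  int E = conn.n_rows, nen = conn.n_cols, ndof = 3 * nen;
  GPCache cache;
  build_cache(nen, nen == 8 ? 2 : 3, cache);
  int ngp = cache.dN.size();
  arma::mat out(ndof * ndof, E);
  arma::mat coords(nen, 3), dNdx, B(6, ndof), ke(ndof, ndof), D(6, 6);
  std::vector<arma::mat> dNdx_gp(ngp);
  std::vector<double> dv(ngp);
  for (int e = 0; e < E; ++e) {
    for (int a = 0; a < nen; ++a)
      coords.row(a) = nodes.row(conn(e, a) - 1);
    D = arma::reshape(Dmat.col(e), 6, 6);
    ke.zeros();
    double vol = 0.0;
    arma::mat bbar_mean(nen, 3, arma::fill::zeros);
    for (int g = 0; g < ngp; ++g) {
      double detJ = cart_deriv(coords, cache.dN[g], dNdx_gp[g]);
      if (detJ <= 0) Rcpp::stop("non-positive Jacobian in element %d", e + 1);
      dv[g] = detJ * cache.w[g];
      if (bbar) {
        vol += dv[g];
        bbar_mean += dNdx_gp[g] * dv[g];
      }
    }
    if (bbar) bbar_mean /= vol;
    for (int g = 0; g < ngp; ++g) {
      fill_B(dNdx_gp[g], B);
      if (bbar) {
        for (int a = 0; a < nen; ++a)
          for (int i = 0; i < 3; ++i) {
            double corr = (bbar_mean(a, i) - dNdx_gp[g](a, i)) / 3.0;
            B(0, 3 * a + i) += corr;
            B(1, 3 * a + i) += corr;
            B(2, 3 * a + i) += corr;
          }
      }
      ke += B.t() * D * B * dv[g];
    }
    out.col(e) = arma::vectorise(ke);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_hex_recover(const arma::mat &nodes, const arma::imat &conn,
                     const arma::mat &Dmat, const arma::vec &u, bool bbar) {
  int E = conn.n_rows, nen = conn.n_cols, ndof = 3 * nen;
  GPCache cache;
  build_cache(nen, nen == 8 ? 2 : 3, cache);
  int ngp = cache.dN.size();
  arma::mat strain(6, E * ngp), stress(6, E * ngp);
  arma::mat coords(nen, 3), B(6, ndof), D(6, 6);
  arma::vec ue(ndof);
  std::vector<arma::mat> dNdx_gp(ngp);
  std::vector<double> dv(ngp);
  for (int e = 0; e < E; ++e) {
    for (int a = 0; a < nen; ++a) {
      coords.row(a) = nodes.row(conn(e, a) - 1);
      for (int i = 0; i < 3; ++i) ue(3 * a + i) = u(3 * (conn(e, a) - 1) + i);
    }
    D = arma::reshape(Dmat.col(e), 6, 6);
    double vol = 0.0;
    arma::mat bbar_mean(nen, 3, arma::fill::zeros);
    for (int g = 0; g < ngp; ++g) {
      double detJ = cart_deriv(coords, cache.dN[g], dNdx_gp[g]);
      dv[g] = detJ * cache.w[g];
      if (bbar) { vol += dv[g]; bbar_mean += dNdx_gp[g] * dv[g]; }
    }
    if (bbar) bbar_mean /= vol;
    for (int g = 0; g < ngp; ++g) {
      fill_B(dNdx_gp[g], B);
      if (bbar) {
        for (int a = 0; a < nen; ++a)
          for (int i = 0; i < 3; ++i) {
            double corr = (bbar_mean(a, i) - dNdx_gp[g](a, i)) / 3.0;
            B(0, 3 * a + i) += corr;
            B(1, 3 * a + i) += corr;
            B(2, 3 * a + i) += corr;
          }
      }
      arma::vec eps = B * ue;
      strain.col(e * ngp + g) = eps;
      stress.col(e * ngp + g) = D * eps;
    }
  }
  return List::create(_["strain"] = strain, _["stress"] = stress,
                      _["ngp"] = ngp);
}

// closest point on a single triangle (Ericson, Real-Time Collision Detection)
static void closest_on_tri(const arma::rowvec &p, const arma::rowvec &a,
                           const arma::rowvec &b, const arma::rowvec &c,
                           arma::rowvec &out, double &u, double &v, double &w) {
  arma::rowvec ab = b - a, ac = c - a, ap = p - a;
  double d1 = arma::dot(ab, ap), d2 = arma::dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { out = a; u = 1; v = 0; w = 0; return; }
  arma::rowvec bp = p - b;
  double d3 = arma::dot(ab, bp), d4 = arma::dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { out = b; u = 0; v = 1; w = 0; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    out = a + t * ab; u = 1 - t; v = t; w = 0; return;
  }
  arma::rowvec cp = p - c;
  double d5 = arma::dot(ab, cp), d6 = arma::dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { out = c; u = 0; v = 0; w = 1; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    out = a + t * ac; u = 1 - t; v = 0; w = t; return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    out = b + t * (c - b); u = 0; v = 1 - t; w = t; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double vv = vb * denom, ww = vc * denom;
  out = a + ab * vv + ac * ww;
  u = 1 - vv - ww; v = vv; w = ww;
}

// [[Rcpp::export]]
List cpp_closest_point_trimesh(const arma::mat &P, const arma::mat &V,
                               const arma::imat &F) {
  int n = P.n_rows, m = F.n_rows;
  arma::mat out(n, 3), bary(n, 3);
  arma::vec dist(n);
  arma::ivec tri(n);
  for (int i = 0; i < n; ++i) {
    double best = arma::datum::inf;
    arma::rowvec bestp(3), q(3);
    int bestt = 0;
    double bu = 0, bv = 0, bw = 0, u, v, w;
    arma::rowvec p = P.row(i);
    for (int t = 0; t < m; ++t) {
      closest_on_tri(p, V.row(F(t, 0) - 1), V.row(F(t, 1) - 1),
                     V.row(F(t, 2) - 1), q, u, v, w);
      double d2 = arma::dot(p - q, p - q);
      if (d2 < best) {
        best = d2; bestp = q; bestt = t; bu = u; bv = v; bw = w;
      }
    }
    out.row(i) = bestp;
    dist(i) = std::sqrt(best);
    tri(i) = bestt + 1;
    bary(i, 0) = bu; bary(i, 1) = bv; bary(i, 2) = bw;
  }
  return List::create(_["point"] = out, _["distance"] = dist,
                      _["triangle"] = tri, _["bary"] = bary);
}
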