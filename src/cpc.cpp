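// Core numerics: Lawson-Hanson non-negative least squares and the sliding
// 3x3x3 neighborhood sweep fitting the 4x4 probability-change matrix at
// every interior voxel. Kept in C++ because the sweep performs ~4 NNLS
// solves per voxel over whole volumes.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Solve min ||A x - b||_2 s.t. x >= 0 (Lawson & Hanson active set).
// Columns of A that are identically zero never enter the passive set and
// keep coefficient 0. Returns the solution; rss is the squared residual.
static arma::vec nnls_lawson_hanson(const arma::mat& A, const arma::vec& b,
                                    double& rss) {
  const arma::uword n = A.n_cols;
  arma::vec x(n, arma::fill::zeros);
  std::vector<bool> passive(n, false);
  arma::vec resid = b;
  const double tol = 1e-12 * std::max(1.0, arma::norm(b, 2));

  for (arma::uword iter = 0; iter < 30 * n; ++iter) {
    // gradient of the active (zero) variables
    arma::vec w = A.t() * resid;
    int best = -1;
    double wmax = tol;
    for (arma::uword j = 0; j < n; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); best = (int)j; }
    }
    if (best < 0) break;  // KKT satisfied
    passive[best] = true;

    // inner loop: solve on the passive set, step back if infeasible
    for (;;) {
      arma::uvec p_idx;
      {
        std::vector<arma::uword> tmp;
        for (arma::uword j = 0; j < n; ++j) if (passive[j]) tmp.push_back(j);
        p_idx = arma::uvec(tmp);
      }
      arma::mat Ap = A.cols(p_idx);
      arma::vec z;
      bool ok = arma::solve(z, Ap, b, arma::solve_opts::no_approx);
      if (!ok) z = arma::pinv(Ap) * b;

      if (z.min() > 0) {
        x.zeros();
        for (arma::uword k = 0; k < p_idx.n_elem; ++k) x(p_idx(k)) = z(k);
        break;
      }
      // find the limiting feasible step
      double alpha = arma::datum::inf;
      for (arma::uword k = 0; k < p_idx.n_elem; ++k) {
        if (z(k) <= 0) {
          double xk = x(p_idx(k));
          double a = xk / (xk - z(k));
          if (a < alpha) alpha = a;
        }
      }
      for (arma::uword k = 0; k < p_idx.n_elem; ++k) {
        arma::uword j = p_idx(k);
        x(j) += alpha * (z(k) - x(j));
        if (x(j) <= 1e-14) { x(j) = 0.0; passive[j] = false; }
      }
      bool any_passive = false;
      for (arma::uword j = 0; j < n; ++j) any_passive = any_passive || passive[j];
      if (!any_passive) break;
    }
    resid = b - A * x;
  }
  rss = arma::dot(resid, resid);
  return x;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_nnls")]]
List cpp_nnls(const arma::mat& A, const arma::vec& b) {
  if (A.n_rows != b.n_elem) stop("nrow(A) must equal length(b)");
  if (A.n_rows < A.n_cols) stop("underdetermined system: m < n");
  double rss = 0.0;
  arma::vec x = nnls_lawson_hanson(A, b, rss);
  return List::create(_["coef"] = x, _["rss"] = rss);
}

// Zero components below tau, rescale survivors to sum 1.
// Row must have positive sum; returns false if all components vanish.
static bool threshold_row(double* p, double tau) {
  double s = 0.0;
  for (int k = 0; k < 4; ++k) { if (p[k] < tau) p[k] = 0.0; s += p[k]; }
  if (s <= 0.0) return false;
  for (int k = 0; k < 4; ++k) p[k] /= s;
  return true;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_cpc_sweep")]]
List cpp_cpc_sweep(NumericVector pt, NumericVector ptt, LogicalVector valid,
                   IntegerVector dims, double tau, double cap,
                   int radius, int min_valid) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  // pt/ptt are nx*ny*nz*4 arrays, channel-major last (g,w,c,b)
  auto at = [&](const NumericVector& v, R_xlen_t vox, int ch) {
    return v[vox + nvox * ch];
  };

  NumericVector channels((R_xlen_t)nvox * 16);   // (i-1)*4+j per source i, target j
  NumericVector residuals((R_xlen_t)nvox * 4);   // per target tissue
  LogicalVector identifiable((R_xlen_t)nvox * 4); // per source tissue
  LogicalVector mask(nvox);

  const int side = 2 * radius + 1;
  const int max_rows = side * side * side;
  arma::mat design(max_rows, 4);
  arma::mat response(max_rows, 4);

  for (int z = radius; z < nz - radius; ++z)
    for (int y = radius; y < ny - radius; ++y)
      for (int x = radius; x < nx - radius; ++x) {
        int m = 0;
        for (int dz = -radius; dz <= radius; ++dz)
          for (int dy = -radius; dy <= radius; ++dy)
            for (int dx = -radius; dx <= radius; ++dx) {
              R_xlen_t vox = (R_xlen_t)(x + dx) +
                             (R_xlen_t)nx * ((y + dy) + (R_xlen_t)ny * (z + dz));
              if (!valid[vox]) continue;
              double rowt[4], rowtt[4];
              for (int k = 0; k < 4; ++k) {
                rowt[k] = at(pt, vox, k);
                rowtt[k] = at(ptt, vox, k);
              }
              if (!threshold_row(rowt, tau) || !threshold_row(rowtt, tau))
                continue;
              for (int k = 0; k < 4; ++k) {
                design(m, k) = rowt[k];
                response(m, k) = rowtt[k];
              }
              ++m;
            }
        R_xlen_t center = (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (m < min_valid || m < 4) continue;

        arma::mat A = design.rows(0, m - 1);
        arma::mat B = response.rows(0, m - 1);
        for (int src = 0; src < 4; ++src)
          identifiable[center + nvox * src] = arma::any(A.col(src) != 0.0);
        for (int tgt = 0; tgt < 4; ++tgt) {
          double rss = 0.0;
          arma::vec f = nnls_lawson_hanson(A, B.col(tgt), rss);
          for (int src = 0; src < 4; ++src) {
            double v = std::min(f(src), cap);
            channels[center + nvox * (R_xlen_t)(src * 4 + tgt)] = v;
          }
          residuals[center + nvox * (R_xlen_t)tgt] = rss;
        }
        mask[center] = true;
      }

  channels.attr("dim") = IntegerVector::create(nx, ny, nz, 16);
  residuals.attr("dim") = IntegerVector::create(nx, ny, nz, 4);
  identifiable.attr("dim") = IntegerVector::create(nx, ny, nz, 4);
  mask.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(_["channels"] = channels, _["validity_mask"] = mask,
                      _["identifiable"] = identifiable,
                      _["fit_residual"] = residuals);
}
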