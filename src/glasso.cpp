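#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Block coordinate descent for the graphical lasso.
// Maximizes log det(Theta) - tr(S Theta) - rho * ||Theta||_1 by cycling
// over columns of the working covariance W = Theta^{-1}; each column
// update solves min_b 0.5 b' W11 b - s12' b + rho |b|_1 by coordinate
// descent with soft-thresholding.
// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double rho, int maxit, double tol,
                      const arma::mat& w_warm, const arma::mat& b_warm) {
  const uword p = S.n_rows;
  mat W, B; // B(k, j): coefficient of variable k (k != j) in column j's lasso
  if (w_warm.n_rows == p) {
    W = w_warm;
    W.diag() = S.diag() + rho;
  } else {
    W = S;
    W.diag() += rho;
  }
  if (b_warm.n_rows == p) B = b_warm; else B = zeros<mat>(p, p);

  double offmean = 0.0;
  if (p > 1) {
    mat offS = abs(S);
    offS.diag().zeros();
    offmean = accu(offS) / (double)(p * (p - 1));
  }
  if (offmean <= 0) offmean = 1.0;
  const double thr_outer = tol * offmean;
  const double thr_inner = 1e-2 * thr_outer;

  bool converged = (p == 1);
  int it = 0;
  for (it = 0; it < maxit && p > 1; ++it) {
    double max_change = 0.0;
    for (uword j = 0; j < p; ++j) {
      // lasso for column j given W11 (current W without row/col j)
      vec beta = B.col(j);
      beta(j) = 0.0;
      // coordinate descent over k != j, maintaining r = W * beta so each
      // coordinate update costs O(p)
      vec r = W * beta;
      for (int sweep = 0; sweep < 500; ++sweep) {
        double delta = 0.0;
        for (uword k = 0; k < p; ++k) {
          if (k == j) continue;
          double z = S(k, j) - r(k) + W(k, k) * beta(k);
          double nb = soft(z, rho) / W(k, k);
          double d = nb - beta(k);
          if (d != 0.0) {
            r += W.col(k) * d;
            beta(k) = nb;
            if (std::abs(d) > delta) delta = std::abs(d);
          }
        }
        if (delta < thr_inner) break;
      }
      // w12 = W11 * beta
      vec w12 = W * beta;           // includes W(:,j)*beta(j) = 0
      w12 -= W.col(j) * beta(j);    // beta(j) is 0 anyway
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        double d = std::abs(w12(k) - W(k, j));
        if (d > max_change) max_change = d;
        W(k, j) = w12(k);
        W(j, k) = w12(k);
      }
      B.col(j) = beta;
    }
    if (max_change < thr_outer) { converged = true; ++it; break; }
  }

  // recover Theta from W and the final regression coefficients
  mat Theta = zeros<mat>(p, p);
  for (uword j = 0; j < p; ++j) {
    vec beta = B.col(j);
    beta(j) = 0.0;
    double denom = W(j, j) - dot(W.col(j), beta);
    double tjj = 1.0 / denom;
    Theta(j, j) = tjj;
    for (uword k = 0; k < p; ++k) {
      if (k == j) continue;
      Theta(k, j) = -beta(k) * tjj;
    }
  }
  // symmetrize (numerical asymmetry only)
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(
      Rcpp::Named("w") = W,
      Rcpp::Named("theta") = Theta,
      Rcpp::Named("beta") = B,
      Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = converged);
}
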