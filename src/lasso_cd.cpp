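#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Cyclic coordinate descent for the lasso over a descending lambda grid with
// warm starts. Objective: 1/(2n) ||y - X b||^2 + lambda ||b||_1.
// Contract: columns of X have mean 0 and sum of squares exactly n (population
// standardization), y is centered. Under that scaling the coordinate update
// is a plain soft-threshold, and coefficients at lambda >= max|X'y|/n are
// exact zeros.

// K-fold CV mean squared error over a fixed lambda grid. Per fold the
// training block is re-standardized (population scaling; near-constant
// columns dropped), the path is fit by warm-started coordinate descent and
// squared prediction errors on the held-out block are accumulated.
// Returns an L-vector of summed squared errors (divide by n for MSE) and,
// stacked below it, the per-fold MSE matrix (k x L) for SE computation.
// [[Rcpp::export(name = ".cv_path_mse")]]
Rcpp::List cv_path_mse(const arma::mat& X, const arma::vec& y,
                       const arma::vec& lambdas, const arma::ivec& fold,
                       const int k, const double tol = 1e-5,
                       const int maxit = 100000) {
  const arma::uword n = X.n_rows, p = X.n_cols, L = lambdas.n_elem;
  arma::mat fold_mse(k, L, arma::fill::zeros);
  arma::vec fold_n(k, arma::fill::zeros);
  for (int f = 1; f <= k; ++f) {
    arma::uvec te = arma::find(fold == f);
    arma::uvec tr = arma::find(fold != f);
    arma::mat Xtr = X.rows(tr);
    arma::vec ytr = y.elem(tr);
    const double ybar = arma::mean(ytr);
    ytr -= ybar;
    const arma::uword ntr = Xtr.n_rows;
    arma::rowvec mu = arma::mean(Xtr, 0);
    arma::rowvec s(p);
    for (arma::uword j = 0; j < p; ++j) {
      Xtr.col(j) -= mu[j];
      s[j] = std::sqrt(arma::dot(Xtr.col(j), Xtr.col(j)) / ntr);
      if (s[j] > 1e-12) Xtr.col(j) /= s[j];
      else Xtr.col(j).zeros();
    }
    // standardized test block with training statistics
    arma::mat Xte = X.rows(te);
    for (arma::uword j = 0; j < p; ++j) {
      Xte.col(j) -= mu[j];
      if (s[j] > 1e-12) Xte.col(j) /= s[j]; else Xte.col(j).zeros();
    }
    arma::vec beta(p, arma::fill::zeros);
    arma::vec r = ytr;
    arma::vec yte = y.elem(te);
    for (arma::uword l = 0; l < L; ++l) {
      const double lam = lambdas[l];
      for (int it = 0; it < maxit; ++it) {
        double maxdelta = 0.0;
        for (arma::uword j = 0; j < p; ++j) {
          const double bj = beta[j];
          const double z = arma::dot(Xtr.col(j), r) / ntr + bj;
          double bn = 0.0;
          if (z > lam) bn = z - lam;
          else if (z < -lam) bn = z + lam;
          if (bn != bj) {
            r += Xtr.col(j) * (bj - bn);
            beta[j] = bn;
            const double d = std::abs(bn - bj);
            if (d > maxdelta) maxdelta = d;
          }
        }
        if (maxdelta < tol) break;
      }
      arma::vec pred = Xte * beta + ybar;
      fold_mse(f - 1, l) = arma::mean(arma::square(yte - pred));
    }
    fold_n[f - 1] = (double)te.n_elem;
  }
  return Rcpp::List::create(Rcpp::Named("fold_mse") = fold_mse,
                            Rcpp::Named("fold_n") = fold_n);
}

// [[Rcpp::export(name = ".lasso_path_cd")]]
arma::mat lasso_path_cd(const arma::mat& X, const arma::vec& y,
                        const arma::vec& lambdas,
                        const double tol = 1e-7, const int maxit = 100000) {
  const arma::uword n = X.n_rows, p = X.n_cols, L = lambdas.n_elem;
  arma::mat B(p, L, arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);
  arma::vec r = y;  // residual y - X beta
  for (arma::uword l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    for (int it = 0; it < maxit; ++it) {
      double maxdelta = 0.0;
      for (arma::uword j = 0; j < p; ++j) {
        const double bj = beta[j];
        const double z = arma::dot(X.col(j), r) / n + bj;
        double bn = 0.0;
        if (z > lam) bn = z - lam;
        else if (z < -lam) bn = z + lam;
        if (bn != bj) {
          r += X.col(j) * (bj - bn);
          beta[j] = bn;
          const double d = std::abs(bn - bj);
          if (d > maxdelta) maxdelta = d;
        }
      }
      if (maxdelta < tol) break;
    }
    B.col(l) = beta;
  }
  return B;
}
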