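#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Block coordinate-descent estimation of a sparse precision matrix:
// maximize  log det(Omega) - tr(S Omega) - lambda * sum_{i != j} |Omega_ij|.
// The diagonal is unpenalized, so the working covariance W keeps diag(S).
// Each column update solves an l1-penalized quadratic subproblem by
// coordinate descent; exact zeros in Omega come from the soft threshold.

static inline double soft(double x, double lambda) {
  if (x > lambda) return x - lambda;
  if (x < -lambda) return x + lambda;
  return 0.0;
}

// [[Rcpp::export]]
Rcpp::List glasso_cd(const arma::mat& S, double lambda, double tol, int maxit,
                     Rcpp::Nullable<Rcpp::NumericMatrix> W0 = R_NilValue,
                     Rcpp::Nullable<Rcpp::NumericMatrix> B0 = R_NilValue) {
  const int p = S.n_rows;
  arma::mat W = S;
  arma::mat B(p, p, arma::fill::zeros); // B.col(j): beta for column j (entry j unused)
  if (W0.isNotNull()) W = Rcpp::as<arma::mat>(W0.get());
  if (B0.isNotNull()) B = Rcpp::as<arma::mat>(B0.get());

  double offmean = 0.0;
  if (p > 1) {
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j)
        if (i != j) offmean += std::abs(S(i, j));
    offmean /= (double)(p * (p - 1));
  }
  const double thr = tol * (offmean > 0 ? offmean : 1.0);
  const double inner_thr = thr * 1e-2;

  bool converged = (p == 1);
  int it = 0;
  for (it = 0; it < maxit && !converged; ++it) {
    double maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      arma::vec beta = B.col(j);
      for (int inner = 0; inner < 500; ++inner) {
        double bdiff = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double grad = S(k, j);
          for (int l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            grad -= W(k, l) * beta(l);
          }
          double bnew = soft(grad, lambda) / W(k, k);
          double d = std::abs(bnew - beta(k));
          if (d > bdiff) bdiff = d;
          beta(k) = bnew;
        }
        if (bdiff < inner_thr) break;
      }
      B.col(j) = beta;
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (int l = 0; l < p; ++l) {
          if (l == j) continue;
          w += W(k, l) * beta(l);
        }
        double d = std::abs(w - W(k, j));
        if (d > maxdiff) maxdiff = d;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (maxdiff < thr) converged = true;
  }

  // Recover Omega column-wise from the final betas; zero pattern is exact.
  arma::mat Omega(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    double denom = W(j, j);
    for (int k = 0; k < p; ++k)
      if (k != j) denom -= W(k, j) * B(k, j);
    const double o22 = 1.0 / denom;
    Omega(j, j) = o22;
    for (int k = 0; k < p; ++k)
      if (k != j) Omega(k, j) = -B(k, j) * o22;
  }
  // Symmetrize without destroying exact zeros (pattern is symmetric at the
  // optimum; tiny asymmetries are numerical).
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      if (Omega(i, j) == 0.0 || Omega(j, i) == 0.0) {
        Omega(i, j) = 0.0;
        Omega(j, i) = 0.0;
      } else {
        double v = 0.5 * (Omega(i, j) + Omega(j, i));
        Omega(i, j) = v;
        Omega(j, i) = v;
      }
    }

  // KKT residual: W - S = lambda * sign(Omega) off-diagonally.
  double kkt = 0.0;
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < p; ++j) {
      double r;
      if (i == j) {
        r = std::abs(W(i, i) - S(i, i));
      } else if (Omega(i, j) != 0.0) {
        r = std::abs(W(i, j) - S(i, j) - lambda * ((Omega(i, j) > 0) - (Omega(i, j) < 0)));
      } else {
        r = std::max(0.0, std::abs(W(i, j) - S(i, j)) - lambda);
      }
      if (r > kkt) kkt = r;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("Omega") = Omega,
      Rcpp::Named("W") = W,
      Rcpp::Named("B") = B,
      Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("kkt") = kkt);
}
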