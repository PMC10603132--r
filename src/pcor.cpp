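#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Partial correlation of x and y given the columns of Z, defined as the
// Pearson correlation of the OLS residuals of x on Z and y on Z (intercept
// included via centering). Returns c(rho, pvalue, n, k, degenerate).
//
// The QR of the centered conditioning block is rank-checked on the diagonal
// of R; a deficient block falls back to a pseudoinverse solve so a scan over
// thousands of tests never aborts mid-way. Residuals with (numerically) zero
// variance yield rho = 0, p = 1, degenerate = 1.
// [[Rcpp::export]]
Rcpp::NumericVector pcor_engine(const arma::vec& x, const arma::vec& y,
                                const arma::mat& Z) {
  const uword n = x.n_elem;
  const uword k = Z.n_cols;

  vec rx = x - mean(x);
  vec ry = y - mean(y);

  if (k > 0) {
    mat Zc = Z.each_row() - mean(Z, 0);
    mat Q, R;
    bool ok = qr_econ(Q, R, Zc);
    bool full_rank = ok;
    if (ok) {
      const vec d = abs(R.diag());
      const double tol = d.max() * 1e-9;
      if (d.max() <= 0.0 || any(d < tol)) full_rank = false;
    }
    if (full_rank) {
      rx -= Q * (Q.t() * rx);
      ry -= Q * (Q.t() * ry);
    } else {
      // collinear or constant conditioners: minimum-norm projection
      mat Zp = pinv(Zc);
      rx -= Zc * (Zp * rx);
      ry -= Zc * (Zp * ry);
    }
  }

  const double sxx = dot(rx, rx);
  const double syy = dot(ry, ry);
  const double df = static_cast<double>(n) - static_cast<double>(k) - 2.0;
  const double scale = std::max(dot(x - mean(x), x - mean(x)),
                                dot(y - mean(y), y - mean(y)));
  const double eps = std::max(scale, 1.0) * 1e-24;

  double rho, pval, degen = 0.0;
  if (sxx <= eps || syy <= eps || df < 1.0) {
    rho = 0.0;
    pval = 1.0;
    degen = 1.0;
  } else {
    rho = dot(rx, ry) / std::sqrt(sxx * syy);
    if (rho > 1.0) rho = 1.0;
    if (rho < -1.0) rho = -1.0;
    const double r2 = rho * rho;
    if (r2 >= 1.0) {
      pval = 0.0;
    } else {
      const double tstat = rho * std::sqrt(df / (1.0 - r2));
      pval = 2.0 * R::pt(-std::fabs(tstat), df, 1, 0);
    }
  }

  return Rcpp::NumericVector::create(rho, pval,
                                     static_cast<double>(n),
                                     static_cast<double>(k), degen);
}

// Simulate the planted lagged linear system: z[t, j] = sum over links into j
// of coef * z[t - lag, src] + eps[t, j]. eps is (n_total x N) pre-drawn noise;
// links are 0-based column indices. Returns the full (burn-in included) path.
// [[Rcpp::export]]
arma::mat var_recurse(const arma::mat& eps, const arma::ivec& src,
                      const arma::ivec& tgt, const arma::ivec& lag,
                      const arma::vec& coef) {
  mat z = eps;
  const uword T = z.n_rows;
  const uword L = src.n_elem;
  for (uword t = 0; t < T; ++t) {
    for (uword l = 0; l < L; ++l) {
      const sword tl = static_cast<sword>(t) - lag(l);
      if (tl >= 0) z(t, tgt(l)) += coef(l) * z(tl, src(l));
    }
  }
  return z;
}
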