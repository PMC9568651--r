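// Conditional logistic regression for 1:1 matched pairs.
//
// For a pair with covariate difference d = x_case - x_control, the
// conditional likelihood contribution is P(case | pair) = sigma(d' b),
// so the log-likelihood is  l(b) = sum_pairs log sigma(d_i' b)
//                               = sum_pairs -log(1 + exp(-d_i' b)).
// Maximized by Newton-Raphson with step-halving; SEs from the inverse
// observed information at the maximum.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// status codes: 0 ok, 1 degenerate, 2 separated, 3 not_converged
static const double SEP_THRESHOLD = 15.0;

static double cond_loglik(const arma::mat& D, const arma::vec& b) {
  arma::vec eta = D * b;
  double ll = 0.0;
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    double e = eta(i);
    // -log(1 + exp(-e)) computed stably
    ll += (e > 0) ? -std::log1p(std::exp(-e)) : e - std::log1p(std::exp(e));
  }
  return ll;
}

// Newton fit on a pair-difference design matrix D (n_pairs x p).
// The first column is the term tested for separation (methylation).
static void newton_fit(const arma::mat& D, arma::vec& b, arma::vec& se,
                       int& status, int maxit, double tol) {
  const arma::uword n = D.n_rows, p = D.n_cols;
  b.zeros(p);
  se.fill(NA_REAL);
  status = 3;

  // degenerate: methylation differences all (numerically) zero
  if (arma::abs(D.col(0)).max() < 1e-12) { status = 1; return; }

  bool mono_pos = arma::all(D.col(0) >= 0);
  bool mono_neg = arma::all(D.col(0) <= 0);

  double ll = cond_loglik(D, b);
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = D * b;
    arma::vec mu(n);
    for (arma::uword i = 0; i < n; ++i) mu(i) = 1.0 / (1.0 + std::exp(-eta(i)));
    arma::vec score = D.t() * (1.0 - mu);
    arma::vec w = mu % (1.0 - mu);
    arma::mat H = D.t() * (D.each_col() % w);

    if (arma::norm(score, 2) < tol) {
      // a coefficient escaping past the threshold in ANY direction marks a
      // (quasi-)separated likelihood: the "maximum" sits on a flat ridge
      // and Wald inference is meaningless
      if (arma::abs(b).max() > SEP_THRESHOLD) {
        status = (std::abs(b(0)) > SEP_THRESHOLD && (mono_pos || mono_neg))
                   ? 2 : 3;
        return;
      }
      arma::mat Hinv;
      if (!arma::inv_sympd(Hinv, H)) {
        if (!arma::inv(Hinv, H)) { status = 3; return; }
      }
      se = arma::sqrt(Hinv.diag());
      status = 0;
      return;
    }

    arma::vec step;
    if (!arma::solve(step, H, score)) { status = 3; return; }
    // step-halving: insist on likelihood increase
    double scale = 1.0;
    arma::vec bnew = b + step;
    double llnew = cond_loglik(D, bnew);
    int halvings = 0;
    while (llnew < ll && halvings < 30) {
      scale *= 0.5; ++halvings;
      bnew = b + scale * step;
      llnew = cond_loglik(D, bnew);
    }
    b = bnew; ll = llnew;

    if (arma::abs(b).max() > SEP_THRESHOLD) {
      status = (std::abs(b(0)) > SEP_THRESHOLD && (mono_pos || mono_neg))
                 ? 2 : 3;
      return;
    }
  }
  status = 3;
}

//' @noRd
// [[Rcpp::export(name = ".clogit_newton_cpp")]]
List clogit_newton_cpp(const arma::mat& D, int maxit = 50, double tol = 1e-8) {
  arma::vec b, se;
  int status;
  newton_fit(D, b, se, status, maxit, tol);
  return List::create(_["coef"] = b, _["se"] = se, _["status"] = status,
                      _["loglik"] = (status == 0) ? cond_loglik(D, b) : NA_REAL);
}

// Per-probe driver: row j of `mdiff` supplies the methylation difference
// column; `Z` holds shared covariate differences (may have zero columns).
//' @noRd
// [[Rcpp::export(name = ".clogit_fit_matrix_cpp")]]
List clogit_fit_matrix_cpp(const arma::mat& mdiff, const arma::mat& Z,
                           int maxit = 50, double tol = 1e-8) {
  const arma::uword np = mdiff.n_rows, n = mdiff.n_cols, q = Z.n_cols;
  if (q > 0 && Z.n_rows != n) stop("covariate rows must match pair count");
  arma::vec coef(np), se(np);
  arma::ivec status(np);
  coef.fill(NA_REAL); se.fill(NA_REAL);

  arma::mat D(n, 1 + q);
  if (q > 0) D.cols(1, q) = Z;
  arma::vec b, s;
  for (arma::uword j = 0; j < np; ++j) {
    D.col(0) = mdiff.row(j).t();
    int st;
    newton_fit(D, b, s, st, maxit, tol);
    status(j) = st;
    if (st == 0 || st == 2) { coef(j) = b(0); }
    if (st == 0) { se(j) = s(0); }
  }
  return List::create(_["coef"] = coef, _["se"] = se, _["status"] = status);
}
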