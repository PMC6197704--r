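#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Sparse Bayesian regression by iterative hyperparameter re-estimation.
// Design Phi = [bias | kernel columns]; independent Gaussian prior
// precision alpha_i per column; noise variance sigma2. Per iteration:
//   Sigma = (Phi_a' Phi_a / sigma2 + diag(alpha_a))^-1   (active set a)
//   mu    = Sigma Phi_a' y / sigma2
//   gamma_i = 1 - alpha_i Sigma_ii
//   alpha_i <- gamma_i / mu_i^2
//   sigma2  <- ||y - Phi_a mu||^2 / (n - sum gamma)
// Columns with alpha above alpha_prune are removed (never the bias,
// column 0). Convergence on max |delta log alpha| < tol (or
// |delta log sigma2| when alpha is frozen).
// [[Rcpp::export]]
Rcpp::List rvr_fit_arma(const arma::mat& Phi, const arma::vec& y,
                        arma::vec alpha, double sigma2,
                        double alpha_prune, double tol, int max_iter,
                        bool update_alpha, bool update_sigma2,
                        double jitter_rel) {
  const uword n = Phi.n_rows;
  const uword M = Phi.n_cols;
  if (alpha.n_elem != M) Rcpp::stop("rvr_fit: alpha length mismatch");

  const mat PtP = Phi.t() * Phi;
  const vec Pty = Phi.t() * y;
  const double yty = dot(y, y);
  const double s2_floor = 1e-12 * (yty / n + 1e-30);

  uvec active = regspace<uvec>(0, M - 1);
  vec alpha_a = alpha;
  vec mu, gam;
  std::vector<double> ml;
  bool converged = false, flagged = false;
  int iters = 0;
  const double LOG2PI = std::log(2.0 * M_PI);

  auto posterior = [&](const uvec& act, const vec& al, double s2,
                       vec& mu_out, vec& gam_out, double& logdetA) {
    mat A = PtP.submat(act, act) / s2;
    A.diag() += al;
    mat Sigma;
    if (!inv_sympd(Sigma, A)) {
      A.diag() += jitter_rel * trace(A);
      if (!inv_sympd(Sigma, A))
        Rcpp::stop("rvr_fit: posterior covariance inversion failed");
    }
    mu_out = Sigma * Pty.elem(act) / s2;
    gam_out = 1.0 - al % Sigma.diag();
    double sign;
    log_det(logdetA, sign, A);
  };

  for (int it = 1; it <= max_iter; ++it) {
    iters = it;
    double logdetA;
    posterior(active, alpha_a, sigma2, mu, gam, logdetA);
    if (!mu.is_finite())
      Rcpp::stop("rvr_fit: NaN in posterior mean at iteration %d "
                 "(sigma2=%g, active=%d)", it, sigma2, (int)active.n_elem);

    // marginal log-likelihood via determinant/inversion lemmas
    double logdetC = n * std::log(sigma2) - accu(log(alpha_a)) + logdetA;
    double yCy = (yty - dot(Pty.elem(active), mu)) / sigma2;
    ml.push_back(-0.5 * (n * LOG2PI + logdetC + yCy));

    // hyperparameter updates
    vec alpha_new = alpha_a;
    if (update_alpha) {
      for (uword j = 0; j < active.n_elem; ++j) {
        double m2 = mu(j) * mu(j);
        double a = (m2 > 0) ? gam(j) / m2 : 1e300;
        if (!std::isfinite(a) || a < 0) a = 1e300;
        alpha_new(j) = a;
      }
    }
    double sigma2_new = sigma2;
    if (update_sigma2) {
      vec r = y - Phi.cols(active) * mu;
      double denom = n - accu(gam);
      if (denom <= 1e-10) { denom = 1e-10; flagged = true; }
      sigma2_new = dot(r, r) / denom;
      if (sigma2_new <= s2_floor) { sigma2_new = s2_floor; flagged = true; }
    }

    // prune (never the bias, original column 0)
    uvec keep = find((alpha_new <= alpha_prune) || (active == 0));
    double delta;
    if (update_alpha) {
      vec dl = abs(log(alpha_new.elem(keep)) - log(alpha_a.elem(keep)));
      delta = dl.max();
    } else if (update_sigma2) {
      delta = std::fabs(std::log(sigma2_new) - std::log(sigma2));
    } else {
      delta = 0.0;
    }

    active = active.elem(keep);
    alpha_a = alpha_new.elem(keep);
    sigma2 = sigma2_new;

    if (delta < tol) { converged = true; break; }
  }

  // final posterior under the converged hyperparameters
  double logdetA;
  posterior(active, alpha_a, sigma2, mu, gam, logdetA);

  return Rcpp::List::create(
      Rcpp::Named("active") = Rcpp::IntegerVector(active.begin(), active.end()),
      Rcpp::Named("mu") = mu,
      Rcpp::Named("alpha") = alpha_a,
      Rcpp::Named("gamma") = gam,
      Rcpp::Named("sigma2") = sigma2,
      Rcpp::Named("n_iter") = iters,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("flagged") = flagged,
      Rcpp::Named("ml") = ml);
}
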