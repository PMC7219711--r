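// Conjugate Gibbs sampler for the two-stage hierarchical model
//   stage 1:  y_c = W_c delta_c + e,   e ~ N(0, sigma2_c I),  delta_c = (alpha_c, beta_c)
//   stage 2:  delta_c = Delta' x_c + pi_c,  pi_c ~ MVN(0, Sigma)
// with priors  vec(Delta) ~ N(vec(Deltabar), (A I)^{-1} x Sigma),
//   Sigma ~ IW(nu, V),  sigma2_c ~ nu0 * s02 / chisq(nu0).
// All randomness comes from R's RNG so set.seed() governs the draws.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double r_norm() { return R::norm_rand(); }

// lower-triangular Bartlett factor for Wishart(df, S), S = LS LS'
static mat wishart_root(double df, const mat& LS) {
  const uword p = LS.n_rows;
  mat A(p, p, fill::zeros);
  for (uword i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (uword j = 0; j < i; ++j) A(i, j) = r_norm();
  }
  return LS * A;  // W = (LS A)(LS A)'
}

// one draw from inverse-Wishart(nu, V): W ~ Wishart(nu, V^{-1}), return W^{-1}
static mat riwish(double nu, const mat& V) {
  mat LS = chol(inv_sympd(V), "lower");
  mat R = wishart_root(nu, LS);
  mat W = R * R.t();
  return inv_sympd(W);
}

// block 1: per-country coefficient pairs from their MVN full conditionals
static mat draw_delta_block(const cube& WtW, const mat& Wty,
                            const vec& sigma2, const mat& Sigma_inv,
                            const mat& prior_mean) {
  const uword N = Wty.n_cols;
  mat out(2, N);
  for (uword c = 0; c < N; ++c) {
    mat prec = WtW.slice(c) / sigma2(c) + Sigma_inv;
    mat C = inv_sympd(prec);
    vec m = C * (Wty.col(c) / sigma2(c) + Sigma_inv * prior_mean.col(c));
    vec z(2);
    z(0) = r_norm(); z(1) = r_norm();
    out.col(c) = m + chol(C, "lower") * z;
  }
  return out;
}

// block 2: per-country error variances from scaled inverse chi-square
static vec draw_sigma2_block(const cube& WtW, const mat& Wty, const vec& yty,
                             const vec& Tobs, const mat& delta,
                             double nu0, double s02) {
  const uword N = Wty.n_cols;
  vec out(N);
  for (uword c = 0; c < N; ++c) {
    vec d = delta.col(c);
    double ssr = yty(c) - 2.0 * dot(d, Wty.col(c)) +
      as_scalar(d.t() * WtW.slice(c) * d);
    if (ssr < 0) ssr = 0;  // numerical guard
    out(c) = (nu0 * s02 + ssr) / R::rchisq(nu0 + Tobs(c));
  }
  return out;
}

// block 3: second-stage coefficient matrix from its matrix-normal conditional
static mat draw_Delta_block(const mat& X, const mat& D, const mat& Sigma,
                            double A, const mat& Deltabar) {
  const uword k = X.n_cols;
  mat P = X.t() * X + A * eye(k, k);
  mat Pinv = inv_sympd(P);
  mat Dtilde = Pinv * (X.t() * D + A * Deltabar);
  mat Z(k, 2);
  for (uword i = 0; i < k; ++i) { Z(i, 0) = r_norm(); Z(i, 1) = r_norm(); }
  // vec covariance Sigma (x) Pinv
  return Dtilde + chol(Pinv, "lower") * Z * chol(Sigma, "upper");
}

// block 4: coefficient covariance from its inverse-Wishart conditional
static mat draw_Sigma_block(const mat& E, double nu, const mat& V) {
  return riwish(nu + (double)E.n_rows, V + E.t() * E);
}

// [[Rcpp::export]]
arma::mat cpp_draw_delta(const arma::cube& WtW, const arma::mat& Wty,
                         const arma::vec& sigma2, const arma::mat& Sigma,
                         const arma::mat& prior_mean) {
  return draw_delta_block(WtW, Wty, sigma2, inv_sympd(Sigma), prior_mean);
}

// [[Rcpp::export]]
arma::vec cpp_draw_sigma2(const arma::cube& WtW, const arma::mat& Wty,
                          const arma::vec& yty, const arma::vec& Tobs,
                          const arma::mat& delta, double nu0, double s02) {
  return draw_sigma2_block(WtW, Wty, yty, Tobs, delta, nu0, s02);
}

// [[Rcpp::export]]
arma::mat cpp_draw_Delta(const arma::mat& X, const arma::mat& D,
                         const arma::mat& Sigma, double A,
                         const arma::mat& Deltabar) {
  return draw_Delta_block(X, D, Sigma, A, Deltabar);
}

// [[Rcpp::export]]
arma::mat cpp_draw_Sigma(const arma::mat& E, double nu, const arma::mat& V) {
  return draw_Sigma_block(E, nu, V);
}

// [[Rcpp::export]]
Rcpp::List cpp_gibbs(const arma::cube& WtW, const arma::mat& Wty,
                     const arma::vec& yty, const arma::vec& Tobs,
                     const arma::mat& X, double A, const arma::mat& Deltabar,
                     double nu, const arma::mat& V, double nu0, double s02,
                     int n_iter, int burn_in, int thin) {
  const uword N = Wty.n_cols;
  const uword k = X.n_cols;
  const int n_keep = (n_iter - burn_in) / thin;
  if (n_keep <= 0) Rcpp::stop("no retained draws: check n_iter/burn_in/thin");

  // initialize at lightly ridged per-country least squares
  mat delta(2, N);
  for (uword c = 0; c < N; ++c) {
    delta.col(c) = solve(WtW.slice(c) + 1e-8 * eye(2, 2), Wty.col(c));
  }
  vec sigma2(N, fill::value(s02));
  mat Sigma = eye(2, 2);
  mat Delta(k, 2, fill::zeros);

  cube keep_delta(2, N, n_keep);
  cube keep_Delta(k, 2, n_keep);
  cube keep_Sigma(2, 2, n_keep);
  mat keep_sigma2(N, n_keep);

  int stored = 0;
  for (int it = 1; it <= n_iter; ++it) {
    mat Sigma_inv = inv_sympd(Sigma);
    mat prior_mean = (X * Delta).t();  // 2 x N

    delta = draw_delta_block(WtW, Wty, sigma2, Sigma_inv, prior_mean);
    if (!delta.is_finite())
      Rcpp::stop("sampler divergence at iteration %d (country-coefficient block)", it);

    sigma2 = draw_sigma2_block(WtW, Wty, yty, Tobs, delta, nu0, s02);
    if (!sigma2.is_finite())
      Rcpp::stop("sampler divergence at iteration %d (error-variance block)", it);

    mat D = delta.t();  // N x 2
    Delta = draw_Delta_block(X, D, Sigma, A, Deltabar);
    if (!Delta.is_finite())
      Rcpp::stop("sampler divergence at iteration %d (second-stage coefficient block)", it);

    Sigma = draw_Sigma_block(D - X * Delta, nu, V);
    if (!Sigma.is_finite())
      Rcpp::stop("sampler divergence at iteration %d (covariance block)", it);

    if (it > burn_in && (it - burn_in) % thin == 0 && stored < n_keep) {
      keep_delta.slice(stored) = delta;
      keep_Delta.slice(stored) = Delta;
      keep_Sigma.slice(stored) = Sigma;
      keep_sigma2.col(stored) = sigma2;
      ++stored;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("delta") = keep_delta,
    Rcpp::Named("Delta") = keep_Delta,
    Rcpp::Named("Sigma") = keep_Sigma,
    Rcpp::Named("sigma2") = keep_sigma2,
    Rcpp::Named("n_keep") = stored);
}
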