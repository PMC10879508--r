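// Profiled marginal likelihood for grouped linear mixed models.
//
// Per group j with design blocks X_j (n_j x p), Z_j (n_j x q) and response
// y_j, the marginal covariance is V_j = Z_j Sigma Z_j' + sigma2 I. Writing
// G = Sigma / sigma2 = L L' (L lower triangular, log-Cholesky parameterized
// by theta), the Woodbury identity gives
//   V_j^{-1} = (1/sigma2) (I - Z_j L M_j^{-1} L' Z_j'),
//   log|V_j| = n_j log sigma2 + log|M_j|,   M_j = I_q + L' (Z_j'Z_j) L,
// so the profiled deviance needs only the per-group cross-product matrix of
// [X_j, Z_j, y_j] -- never the raw rows. beta is profiled by GLS and sigma2
// in closed form (ML, divisor N), leaving optimization over theta alone.
//
// The gradient follows from the envelope theorem (beta and sigma2 are
// stationary at their profiled values): with u_j = Z_j'(y_j - X_j beta) and
// v_j = M_j^{-1} L' u_j,
//   dl/dL = sum_j [ (u_j - Szz_j L v_j) v_j' / sigma2 - (M_j^{-1} L' Szz_j)' ],
// chained through the log-diagonal of L.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat theta_to_L(const vec& theta, const int q) {
  mat L(q, q, fill::zeros);
  int k = 0;
  for (int j = 0; j < q; ++j)
    for (int i = j; i < q; ++i) {
      const double v = theta(k++);
      L(i, j) = (i == j) ? std::exp(v) : v;
    }
  return L;
}

// Accumulate the profiled pieces; optionally keep per-group M^{-1}.
// Returns false on numerical failure.
static bool accumulate(const mat& L, const cube& C,
                       const int p, const int q,
                       mat& A, vec& b, double& c, double& logdet,
                       cube* Minv_store) {
  const int J = C.n_slices;
  const int yi = p + q;
  A.zeros(p, p); b.zeros(p); c = 0.0; logdet = 0.0;
  mat M, R, Rinv, Minv, K, SxzK;
  for (int j = 0; j < J; ++j) {
    const mat& Cj = C.slice(j);
    const mat Szz = Cj.submat(p, p, yi - 1, yi - 1);
    M = L.t() * Szz * L;
    M.diag() += 1.0;
    if (!chol(R, M, "lower")) return false;
    logdet += 2.0 * accu(log(R.diag()));
    Rinv = inv(trimatl(R));
    Minv = Rinv.t() * Rinv;
    if (Minv_store) Minv_store->slice(j) = Minv;
    K = L * Minv * L.t();
    const mat Sxz = Cj.submat(0, p, p - 1, yi - 1);
    SxzK = Sxz * K;
    A += Cj.submat(0, 0, p - 1, p - 1) - SxzK * Sxz.t();
    const vec Szy = Cj.submat(p, yi, yi - 1, yi);
    b += vec(Cj.submat(0, yi, p - 1, yi)) - SxzK * Szy;
    c += Cj(yi, yi) - dot(Szy, K * Szy);
  }
  return A.is_finite() && std::isfinite(c);
}

// Profiled log-likelihood (ML) at theta; -Inf on numerical failure.
// [[Rcpp::export(name = ".profiled_ll_cpp")]]
double profiled_ll_cpp(const arma::vec& theta, const arma::cube& C,
                       const arma::vec& n, const int p, const int q) {
  const double N = accu(n);
  const mat L = theta_to_L(theta, q);
  mat A; vec b; double c, logdet;
  if (!accumulate(L, C, p, q, A, b, c, logdet, nullptr))
    return -datum::inf;
  vec beta;
  if (!solve(beta, A, b, solve_opts::no_approx)) return -datum::inf;
  const double rss = c - dot(b, beta);
  if (!(rss > 0.0) || !std::isfinite(rss)) return -datum::inf;
  const double sigma2 = rss / N;
  return -0.5 * (N * std::log(2.0 * datum::pi) + N * std::log(sigma2) +
                 logdet + N);
}

// Profiled negative log-likelihood and its analytic theta-gradient.
// [[Rcpp::export(name = ".profiled_nll_grad_cpp")]]
Rcpp::List profiled_nll_grad_cpp(const arma::vec& theta, const arma::cube& C,
                                 const arma::vec& n, const int p,
                                 const int q) {
  const double N = accu(n);
  const int J = C.n_slices;
  const int yi = p + q;
  const mat L = theta_to_L(theta, q);
  const int m = q * (q + 1) / 2;
  cube Minv(q, q, J);
  mat A; vec b; double c, logdet;
  if (!accumulate(L, C, p, q, A, b, c, logdet, &Minv))
    return Rcpp::List::create(Rcpp::Named("nll") = R_PosInf,
                              Rcpp::Named("grad") = Rcpp::NumericVector(m));
  vec beta;
  if (!solve(beta, A, b, solve_opts::no_approx))
    return Rcpp::List::create(Rcpp::Named("nll") = R_PosInf,
                              Rcpp::Named("grad") = Rcpp::NumericVector(m));
  const double rss = c - dot(b, beta);
  if (!(rss > 0.0) || !std::isfinite(rss))
    return Rcpp::List::create(Rcpp::Named("nll") = R_PosInf,
                              Rcpp::Named("grad") = Rcpp::NumericVector(m));
  const double sigma2 = rss / N;
  const double ll = -0.5 * (N * std::log(2.0 * datum::pi) +
                            N * std::log(sigma2) + logdet + N);
  mat gL(q, q, fill::zeros);
  vec u(q), v(q), Lv(q);
  for (int j = 0; j < J; ++j) {
    const mat& Cj = C.slice(j);
    const mat Szz = Cj.submat(p, p, yi - 1, yi - 1);
    const mat Szx = Cj.submat(p, 0, yi - 1, p - 1);
    const vec Szy = Cj.submat(p, yi, yi - 1, yi);
    u = Szy - Szx * beta;
    v = Minv.slice(j) * (L.t() * u);
    Lv = L * v;
    gL += (u - Szz * Lv) * v.t() / sigma2 - (Minv.slice(j) * (L.t() * Szz)).t();
  }
  // chain rule through theta: off-diagonals pass through, diagonal of L is
  // exp(theta); gradient of the NEGATIVE log-likelihood.
  vec grad(m);
  int k = 0;
  for (int jj = 0; jj < q; ++jj)
    for (int ii = jj; ii < q; ++ii) {
      double g = gL(ii, jj);
      if (ii == jj) g *= L(ii, ii);
      grad(k++) = -g;
    }
  return Rcpp::List::create(Rcpp::Named("nll") = -ll,
                            Rcpp::Named("grad") = grad);
}

// Full profiled fit at theta: beta, sigma2, loglik, scaled information
// (A = sigma2 * X'V^{-1}X) and per-group BLUPs.
// [[Rcpp::export(name = ".profiled_fit_cpp")]]
Rcpp::List profiled_fit_cpp(const arma::vec& theta, const arma::cube& C,
                            const arma::vec& n, const int p, const int q) {
  const double N = accu(n);
  const int J = C.n_slices;
  const int yi = p + q;
  const mat L = theta_to_L(theta, q);
  mat A; vec b; double c, logdet;
  if (!accumulate(L, C, p, q, A, b, c, logdet, nullptr))
    Rcpp::stop("singular per-group covariance during profiled fit");
  const vec beta = solve(A, b, solve_opts::no_approx);
  const double rss = c - dot(b, beta);
  if (!(rss > 0.0))
    Rcpp::stop("non-positive residual sum of squares in profiled fit");
  const double sigma2 = rss / N;
  const double ll = -0.5 * (N * std::log(2.0 * datum::pi) +
                            N * std::log(sigma2) + logdet + N);
  // BLUPs: b_hat_j = G (I - Szz K)(Szy - Szx beta), in Sigma units.
  const mat G = L * L.t();
  mat blups(J, q);
  for (int j = 0; j < J; ++j) {
    const mat& Cj = C.slice(j);
    const mat Szz = Cj.submat(p, p, yi - 1, yi - 1);
    const mat Szx = Cj.submat(p, 0, yi - 1, p - 1);
    const vec Szy = Cj.submat(p, yi, yi - 1, yi);
    mat M = L.t() * Szz * L;
    M.diag() += 1.0;
    mat R;
    if (!chol(R, M, "lower"))
      Rcpp::stop("singular per-group covariance for group %d", j + 1);
    const mat W = solve(trimatl(R), L.t());
    const mat K = W.t() * W;
    const vec zr = Szy - Szx * beta;
    blups.row(j) = (G * (zr - Szz * (K * zr))).t();
  }
  return Rcpp::List::create(
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("beta") = beta,
    Rcpp::Named("sigma2") = sigma2,
    Rcpp::Named("A") = A,
    Rcpp::Named("G") = G,
    Rcpp::Named("blups") = blups);
}
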