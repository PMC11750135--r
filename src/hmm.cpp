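// Core numerics for the Gaussian-emission HMM: emission log-densities,
// scaled forward-backward, Viterbi decoding, and Baum-Welch EM over a
// cohort concatenation in which the chain resets at each subject boundary.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// Cholesky with escalating diagonal jitter; throws only if hopeless.
static mat safe_chol_lower(const mat& S) {
  mat L;
  double jitter = 0.0;
  for (int attempt = 0; attempt < 7; ++attempt) {
    mat Sj = S;
    if (jitter > 0.0) Sj.diag() += jitter;
    if (chol(L, Sj, "lower")) return L;
    jitter = (jitter == 0.0) ? 1e-10 : jitter * 100.0;
  }
  Rcpp::stop("covariance matrix is not positive definite");
}

// T x k matrix of log N(x_t; mu_j, Sigma_j)
// [[Rcpp::export(name = ".gaussLogDensCpp")]]
arma::mat gauss_log_dens(const arma::mat& X, const arma::mat& means,
                         const arma::cube& covs) {
  const uword T = X.n_rows, N = X.n_cols, k = means.n_rows;
  mat out(T, k);
  for (uword j = 0; j < k; ++j) {
    mat L = safe_chol_lower(covs.slice(j));
    double logdet = 2.0 * accu(log(L.diag()));
    mat Xc = X.each_row() - means.row(j);
    // rows of Z solve L Z' = Xc'
    mat Z = solve(trimatl(L), Xc.t());
    rowvec quad = sum(square(Z), 0);
    out.col(j) = (-0.5 * (N * LOG2PI + logdet) - 0.5 * quad.t());
  }
  return out;
}

struct FBResult {
  mat gamma;
  mat xi;       // k x k, summed over within-segment transitions
  vec gamma0;   // summed gamma at segment starts
  double loglik;
};

static FBResult forward_backward_seg(const mat& logB, const mat& A,
                                     const vec& pi, const uvec& segLens) {
  const uword T = logB.n_rows, k = logB.n_cols;
  FBResult res;
  res.gamma.set_size(T, k);
  res.xi.zeros(k, k);
  res.gamma0.zeros(k);
  res.loglik = 0.0;

  // row-shifted emission probabilities, computed once
  vec shift = max(logB, 1);
  mat B = exp(logB.each_col() - shift);

  uword offset = 0;
  for (uword s = 0; s < segLens.n_elem; ++s) {
    const uword Ts = segLens(s);
    mat alpha(Ts, k), beta(Ts, k);
    vec logc(Ts);
    // scaled forward
    for (uword t = 0; t < Ts; ++t) {
      rowvec a;
      if (t == 0) a = pi.t() % B.row(offset);
      else a = (alpha.row(t - 1) * A) % B.row(offset + t);
      double c = accu(a);
      if (c <= 0 || !std::isfinite(c)) Rcpp::stop("forward recursion underflow");
      alpha.row(t) = a / c;
      logc(t) = std::log(c) + shift(offset + t);
    }
    res.loglik += accu(logc);
    // scaled backward (same scaling constants)
    beta.row(Ts - 1).ones();
    for (uword t = Ts - 1; t-- > 0;) {
      double cnext = std::exp(logc(t + 1) - shift(offset + t + 1));
      vec rhs = A * (B.row(offset + t + 1).t() % beta.row(t + 1).t());
      beta.row(t) = rhs.t() / cnext;
    }
    mat g = alpha % beta;
    g.each_col() /= sum(g, 1);  // guard tiny scaling drift
    res.gamma.rows(offset, offset + Ts - 1) = g;
    res.gamma0 += g.row(0).t();
    // xi sums
    for (uword t = 0; t + 1 < Ts; ++t) {
      mat x = (alpha.row(t).t() *
               (B.row(offset + t + 1) % beta.row(t + 1))) % A;
      double z = accu(x);
      if (z > 0) res.xi += x / z;
    }
    offset += Ts;
  }
  return res;
}

// [[Rcpp::export(name = ".forwardBackwardCpp")]]
Rcpp::List forward_backward(const arma::mat& logB, const arma::mat& A,
                            const arma::vec& pi,
                            const arma::uvec& segLens) {
  FBResult r = forward_backward_seg(logB, A, pi, segLens);
  return Rcpp::List::create(Rcpp::Named("gamma") = r.gamma,
                            Rcpp::Named("xi") = r.xi,
                            Rcpp::Named("gamma0") = r.gamma0,
                            Rcpp::Named("loglik") = r.loglik);
}

// Viterbi over a single segment; ties resolved toward the lower state index.
// [[Rcpp::export(name = ".viterbiCpp")]]
arma::uvec viterbi(const arma::mat& logB, const arma::mat& logA,
                   const arma::vec& logPi) {
  const uword T = logB.n_rows, k = logB.n_cols;
  mat delta(T, k);
  umat psi(T, k, fill::zeros);
  delta.row(0) = logPi.t() + logB.row(0);
  for (uword t = 1; t < T; ++t) {
    for (uword j = 0; j < k; ++j) {
      double best = -datum::inf;
      uword arg = 0;
      for (uword i = 0; i < k; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }  // strict: ties keep lower i
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  uvec path(T);
  double best = -datum::inf;
  for (uword j = 0; j < k; ++j)
    if (delta(T - 1, j) > best) { best = delta(T - 1, j); path(T - 1) = j; }
  for (uword t = T - 1; t-- > 0;) path(t) = psi(t + 1, path(t + 1));
  return path + 1;  // 1-based state labels
}

// Baum-Welch EM on concatenated data with per-subject chain resets.
// Covariances re-estimated as full matrices with `reg` added to the
// diagonal every M-step.
// [[Rcpp::export(name = ".emFitCpp")]]
Rcpp::List em_fit(const arma::mat& X, const arma::uvec& segLens,
                  arma::mat means, arma::cube covs, arma::mat A,
                  arma::vec pi, int maxIter, double tol, double reg) {
  const uword k = means.n_rows, N = X.n_cols;
  std::vector<double> trace;
  double prev = -datum::inf;
  bool converged = false;
  for (int it = 0; it < maxIter; ++it) {
    mat logB = gauss_log_dens(X, means, covs);
    FBResult r = forward_backward_seg(logB, A, pi, segLens);
    trace.push_back(r.loglik);
    if (std::isfinite(prev) &&
        std::fabs(r.loglik - prev) <
            tol * (std::fabs(prev) + 1e-10)) {
      converged = true;
      break;
    }
    prev = r.loglik;
    // M-step
    rowvec w = sum(r.gamma, 0);
    for (uword j = 0; j < k; ++j) {
      if (w(j) < 1e-8) {  // collapsed state: keep mean, reset covariance
        covs.slice(j) = eye(N, N);
        continue;
      }
      rowvec mu = (r.gamma.col(j).t() * X) / w(j);
      means.row(j) = mu;
      mat Xc = X.each_row() - mu;
      mat S = Xc.t() * (Xc.each_col() % r.gamma.col(j)) / w(j);
      S.diag() += reg;
      covs.slice(j) = 0.5 * (S + S.t());
    }
    vec rowsum = sum(r.xi, 1);
    for (uword i = 0; i < k; ++i) {
      if (rowsum(i) > 0) A.row(i) = r.xi.row(i) / rowsum(i);
    }
    double g0 = accu(r.gamma0);
    if (g0 > 0) pi = r.gamma0 / g0;
  }
  if (!converged && !trace.empty()) {
    // evidence must describe the returned parameters, which were updated
    // once more after the last recorded log-likelihood
    mat logB = gauss_log_dens(X, means, covs);
    FBResult r = forward_backward_seg(logB, A, pi, segLens);
    trace.push_back(r.loglik);
  }
  return Rcpp::List::create(
      Rcpp::Named("means") = means, Rcpp::Named("covs") = covs,
      Rcpp::Named("transition") = A, Rcpp::Named("initial") = pi,
      Rcpp::Named("loglikTrace") = trace,
      Rcpp::Named("evidence") = trace.empty() ? R_NegInf : trace.back(),
      Rcpp::Named("converged") = converged);
}
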