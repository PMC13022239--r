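// State-space innovations filter for ARMA errors (Harvey representation).
//
// The zero-mean error process u_t = phi_1 u_{t-1} + ... + e_t + theta_1 e_{t-1} + ...
// is cast as alpha_t = T alpha_{t-1} + R e_t, u_t = alpha_t[0], with state
// dimension r = max(p, q + 1), T the companion matrix of phi and
// R = (1, theta_1, ..., theta_{r-1})'.  The innovation variance is
// concentrated out: the filter runs at unit variance and returns the
// normalized quantities sum(log F_t) and sum(v_t^2 / F_t).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// T M for companion T (phi in first column, identity superdiagonal): O(r^2)
static mat comp_left(const vec& phi, const mat& M) {
  const uword r = phi.n_elem;
  mat out(r, M.n_cols, fill::zeros);
  if (r > 1) out.rows(0, r - 2) = M.rows(1, r - 1);
  out += phi * M.row(0);
  return out;
}

// M T' : companion acting on columns
static mat comp_right(const mat& M, const vec& phi) {
  const uword r = phi.n_elem;
  mat out(M.n_rows, r, fill::zeros);
  if (r > 1) out.cols(0, r - 2) = M.cols(1, r - 1);
  out += M.col(0) * phi.t();
  return out;
}

static vec comp_state(const vec& phi, const vec& a) {
  const uword r = phi.n_elem;
  vec out(r, fill::zeros);
  if (r > 1) out.subvec(0, r - 2) = a.subvec(1, r - 1);
  out += phi * a(0);
  return out;
}

// Stationary state covariance: P = T P T' + R R', by the doubling iteration.
static mat stationary_P(const vec& phi, const vec& Rv) {
  const uword r = phi.n_elem;
  mat T(r, r, fill::zeros);
  T.col(0) = phi;
  for (uword i = 0; i + 1 < r; ++i) T(i, i + 1) = 1.0;
  mat P = Rv * Rv.t();
  mat A = T;
  for (int k = 0; k < 60; ++k) {
    P += A * P * A.t();
    A = A * A;
    if (norm(A, "fro") < 1e-14) break;
  }
  return P;
}

static void pack(const Rcpp::NumericVector& phi_in, const Rcpp::NumericVector& theta_in,
                 vec& phi, vec& Rv) {
  const uword p = phi_in.size(), q = theta_in.size();
  const uword r = std::max(p, q + 1);
  phi = vec(r, fill::zeros);
  for (uword i = 0; i < p; ++i) phi(i) = phi_in[i];
  Rv = vec(r, fill::zeros);
  Rv(0) = 1.0;
  for (uword j = 0; j < q; ++j) Rv(j + 1) = theta_in[j];
}

// Kalman filter pass over z (NA = missing).  Returns normalized innovations,
// their variances, the accumulated log-determinant and weighted SSQ, and the
// end-of-sample filtered state for forecasting.
// [[Rcpp::export]]
Rcpp::List ss_filter_cpp(Rcpp::NumericVector z,
                         Rcpp::NumericVector phi_in,
                         Rcpp::NumericVector theta_in) {
  vec phi, Rv;
  pack(phi_in, theta_in, phi, Rv);
  const uword r = phi.n_elem;
  const int n = z.size();

  mat RRt = Rv * Rv.t();
  mat P = stationary_P(phi, Rv);   // filtered covariance (stationary start)
  vec a(r, fill::zeros);

  Rcpp::NumericVector v_out(n, NA_REAL), F_out(n, NA_REAL);
  double sumlog = 0.0, ssq = 0.0;
  int neff = 0;

  bool steady = false;
  double Fs = 0.0;
  vec Ks;
  mat Ppred_s;

  for (int t = 0; t < n; ++t) {
    const bool miss = Rcpp::NumericVector::is_na(z[t]);
    vec apred = comp_state(phi, a);

    if (steady) {
      if (miss) {
        a = apred;
        P = Ppred_s;          // no update: filtered = predicted
        steady = false;
      } else {
        double v = z[t] - apred(0);
        a = apred + Ks * v;
        sumlog += std::log(Fs);
        ssq += v * v / Fs;
        v_out[t] = v; F_out[t] = Fs;
        ++neff;
      }
      continue;
    }

    mat Ppred = comp_right(comp_left(phi, P), phi) + RRt;
    double F = Ppred(0, 0);
    if (miss) {
      a = apred;
      P = Ppred;
    } else {
      vec K = Ppred.col(0) / F;
      double v = z[t] - apred(0);
      a = apred + K * v;
      mat Pnew = Ppred - K * Ppred.row(0);
      if (norm(Pnew - P, "fro") < 1e-12 * (1.0 + norm(Pnew, "fro"))) {
        steady = true;
        Fs = F; Ks = K; Ppred_s = Ppred;
      }
      P = Pnew;
      sumlog += std::log(F);
      ssq += v * v / F;
      v_out[t] = v; F_out[t] = F;
      ++neff;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("sumlog") = sumlog,
    Rcpp::Named("ssq") = ssq,
    Rcpp::Named("n_eff") = neff,
    Rcpp::Named("v") = v_out,
    Rcpp::Named("F") = F_out,
    Rcpp::Named("a") = a,
    Rcpp::Named("P") = P);
}

// h-step prediction from a filtered state: returns the ARMA-error mean path
// and the unit-variance forecast variances P[0,0].
// [[Rcpp::export]]
Rcpp::List ss_predict_cpp(arma::vec a, arma::mat P,
                          Rcpp::NumericVector phi_in,
                          Rcpp::NumericVector theta_in,
                          int h) {
  vec phi, Rv;
  pack(phi_in, theta_in, phi, Rv);
  mat RRt = Rv * Rv.t();
  Rcpp::NumericVector mean_out(h), var_out(h);
  for (int j = 0; j < h; ++j) {
    a = comp_state(phi, a);
    P = comp_right(comp_left(phi, P), phi) + RRt;
    mean_out[j] = a(0);
    var_out[j] = P(0, 0);
  }
  return Rcpp::List::create(Rcpp::Named("mean") = mean_out,
                            Rcpp::Named("var") = var_out);
}

// Conditional-sum-of-squares residuals: presample innovations set to zero,
// the first max(p) observations conditioned on.
// [[Rcpp::export]]
Rcpp::List css_resid_cpp(Rcpp::NumericVector z,
                         Rcpp::NumericVector phi_in,
                         Rcpp::NumericVector theta_in) {
  const int n = z.size();
  const int p = phi_in.size(), q = theta_in.size();
  Rcpp::NumericVector e(n, 0.0);
  for (int t = p; t < n; ++t) {
    double acc = z[t];
    for (int i = 1; i <= p; ++i)
      if (phi_in[i - 1] != 0.0) acc -= phi_in[i - 1] * z[t - i];
    for (int j = 1; j <= q; ++j)
      if (theta_in[j - 1] != 0.0 && t - j >= p) acc -= theta_in[j - 1] * e[t - j];
    e[t] = acc;
  }
  return Rcpp::List::create(Rcpp::Named("e") = e,
                            Rcpp::Named("n_used") = std::max(n - p, 0));
}
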