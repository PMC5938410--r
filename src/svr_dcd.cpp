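// Sequential minimal optimization for epsilon-insensitive support vector
// regression (the LIBSVM algorithm: equality-constrained bias, second-order
// working-set selection).
//
// Dual in the split variables a = (alpha; alpha*), each in [0, C]:
//
//   min 0.5 a' Qh a + p' a,   p = (eps - y; eps + y),
//   s.t. z' a = 0,  z = (+1...; -1...),  Qh_{st} = z_s z_t K_{i(s) i(t)},
//
// where i(t) = t mod n maps the split index to its sample. The returned
// dual coefficients are beta = alpha - alpha*, the regression weights of
// f(x) = sum_i beta_i k(x_i, x) + b.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

struct SmoResult {
  arma::vec beta;
  double b;
  int iter;
  bool converged;
};

SmoResult smo_solve(const arma::mat& K, const arma::vec& y, double C,
                    double eps, double tol, int max_iter,
                    const arma::vec* warm = nullptr) {
  const int n = static_cast<int>(y.n_elem);
  const int N = 2 * n;
  arma::vec a(N, arma::fill::zeros);
  // z_t: +1 for alpha block, -1 for alpha* block
  auto zsgn = [n](int t) { return t < n ? 1.0 : -1.0; };
  auto samp = [n](int t) { return t < n ? t : t - n; };
  // gradient G = Qh a + p; at a = 0, G = p
  arma::vec G(N);
  for (int t = 0; t < N; ++t)
    G(t) = eps + (t < n ? -y(t) : y(t - n));
  if (warm != nullptr && warm->n_elem == static_cast<arma::uword>(n)) {
    // warm start from a previous beta (feasible if |beta| <= C and
    // sum(beta) == 0, as along an ascending C path)
    arma::vec Kb = K * (*warm);
    for (int q = 0; q < n; ++q) {
      const double b0 = std::min(std::max((*warm)(q), -C), C);
      a(q) = std::max(b0, 0.0);
      a(q + n) = std::max(-b0, 0.0);
    }
    for (int t = 0; t < N; ++t)
      G(t) += zsgn(t) * Kb(samp(t));
  }
  int iter = 0;
  bool converged = false;
  double bias = 0.0;
  for (iter = 0; iter < max_iter; ++iter) {
    // score s_t = -z_t G_t; select i = argmax over I_up
    double m_up = -std::numeric_limits<double>::infinity();
    int i = -1;
    for (int t = 0; t < N; ++t) {
      const double z = zsgn(t);
      const bool in_up = (z > 0 && a(t) < C) || (z < 0 && a(t) > 0);
      if (!in_up) continue;
      const double s = -z * G(t);
      if (s > m_up) { m_up = s; i = t; }
    }
    if (i < 0) { converged = true; break; }
    const int ia = samp(i);
    const double zi = zsgn(i);
    // second-order selection of j over I_low with score < m_up
    double m_low = std::numeric_limits<double>::infinity();
    double best_gain = -1.0;
    int j = -1;
    const double Kii = K(ia, ia);
    for (int t = 0; t < N; ++t) {
      const double z = zsgn(t);
      const bool in_low = (z > 0 && a(t) > 0) || (z < 0 && a(t) < C);
      if (!in_low) continue;
      const double s = -z * G(t);
      if (s < m_low) m_low = s;
      const double diff = m_up - s;
      if (diff > 0) {
        const int ta = samp(t);
        double eta = Kii + K(ta, ta) - 2.0 * K(ia, ta);
        if (eta <= 1e-12) eta = 1e-12;
        const double gain = diff * diff / eta;
        if (gain > best_gain) { best_gain = gain; j = t; }
      }
    }
    bias = (m_up + m_low) / 2.0;
    if (m_up - m_low <= tol || j < 0) { converged = true; break; }
    const int ja = samp(j);
    const double zj = zsgn(j);
    // step t: delta a_i = z_i t, delta a_j = -z_j t
    double eta = Kii + K(ja, ja) - 2.0 * K(ia, ja);
    if (eta <= 1e-12) eta = 1e-12;
    double step = (m_up - (-zj * G(j))) / eta;
    // box clipping
    double hi = (zi > 0) ? (C - a(i)) : a(i);        // t upper from i
    double hj = (zj > 0) ? a(j) : (C - a(j));        // t upper from j
    if (step > hi) step = hi;
    if (step > hj) step = hj;
    if (step <= 0) { converged = true; break; }
    a(i) += zi * step;
    a(j) -= zj * step;
    // gradient update: G_t += Qh_{t i} di + Qh_{t j} dj,
    // Qh_{t s} = z_t z_s K(samp t, samp s); di = z_i t, dj = -z_j t
    for (int t = 0; t < N; ++t) {
      const double z = zsgn(t);
      G(t) += z * step * (K(samp(t), ia) - K(samp(t), ja));
    }
  }
  arma::vec beta(n);
  for (int q = 0; q < n; ++q) beta(q) = a(q) - a(q + n);
  SmoResult res;
  res.beta = beta;
  res.b = bias;
  res.iter = iter;
  res.converged = converged;
  return res;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List svr_smo(const arma::mat& K, const arma::vec& y, double C,
                   double eps, double tol, int max_iter,
                   Rcpp::Nullable<Rcpp::NumericVector> beta0 = R_NilValue) {
  if (K.n_rows != y.n_elem || K.n_cols != y.n_elem)
    Rcpp::stop("kernel matrix dimensions do not match the response length");
  SmoResult r;
  if (beta0.isNotNull()) {
    arma::vec w = Rcpp::as<arma::vec>(beta0.get());
    r = smo_solve(K, y, C, eps, tol, max_iter, &w);
  } else {
    r = smo_solve(K, y, C, eps, tol, max_iter);
  }
  return Rcpp::List::create(
      Rcpp::Named("beta") = r.beta,
      Rcpp::Named("b") = r.b,
      Rcpp::Named("iter") = r.iter,
      Rcpp::Named("converged") = r.converged);
}

// Permutation stream for SVR weight inference: for each column of
// `perm_y` (shuffled standardized response) the SVR is re-solved at fixed
// hyperparameters on the fixed kernel, pseudo primal weights w = X' beta
// are formed, and exceedance counters against the real weights are
// incremented. `two_sided` counts |pseudo| >= |real|, otherwise
// pseudo >= real (ties count as exceedance: conservative).

// [[Rcpp::export]]
Rcpp::List svr_perm_counts(const arma::mat& K, const arma::mat& X,
                           const arma::vec& real_w, const arma::mat& perm_y,
                           double C, double eps, double tol, int max_iter,
                           bool two_sided) {
  const arma::uword P = perm_y.n_cols;
  const arma::uword V = X.n_cols;
  if (real_w.n_elem != V)
    Rcpp::stop("real weight length does not match design columns");
  arma::uvec counts(V, arma::fill::zeros);
  int nonconv = 0;
  for (arma::uword p = 0; p < P; ++p) {
    SmoResult r = smo_solve(K, perm_y.col(p), C, eps, tol, max_iter);
    if (!r.converged) ++nonconv;
    arma::vec w = X.t() * r.beta;
    if (two_sided) {
      counts += (arma::abs(w) >= arma::abs(real_w));
    } else {
      counts += (w >= real_w);
    }
    if ((p + 1u) % 64u == 0u) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("counts") = counts,
      Rcpp::Named("n_nonconverged") = nonconv);
}
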