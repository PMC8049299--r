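// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Exact 1-D total-variation proximal operator on a chain,
//   argmin_x 1/2 ||x - y||^2 + lambda * sum_i |x_i - x_{i+1}|,
// by Condat's direct (taut-string) algorithm. O(n) typical, exact.
static void tv1d_condat(const double *y, double *x, const int n,
                        const double lambda) {
  if (n < 1) return;
  if (n == 1 || lambda <= 0.0) {
    for (int i = 0; i < n; ++i) x[i] = y[i];
    return;
  }
  int k = 0, k0 = 0, kminus = 0, kplus = 0;
  double vmin = y[0] - lambda, vmax = y[0] + lambda;
  double umin = lambda, umax = -lambda;
  const double twolambda = 2.0 * lambda, minlambda = -lambda;
  for (;;) {
    while (k == n - 1) { // reached the last sample: flush pending segments
      if (umin < 0.0) {  // a negative jump is necessary
        do x[k0++] = vmin; while (k0 <= kminus);
        umax = (vmin = y[kminus = k = k0]) + (umin = lambda) - vmax;
      } else if (umax > 0.0) { // a positive jump is necessary
        do x[k0++] = vmax; while (k0 <= kplus);
        umin = (vmax = y[kplus = k = k0]) + (umax = minlambda) - vmin;
      } else { // last segment: constant at the corrected level
        vmin += umin / (k - k0 + 1);
        do x[k0++] = vmin; while (k0 <= k);
        return;
      }
    }
    if ((umin += y[k + 1] - vmin) < minlambda) { // negative jump
      do x[k0++] = vmin; while (k0 <= kminus);
      vmax = (vmin = y[kplus = kminus = k = k0]) + twolambda;
      umin = lambda; umax = minlambda;
    } else if ((umax += y[k + 1] - vmax) > lambda) { // positive jump
      do x[k0++] = vmax; while (k0 <= kplus);
      vmin = (vmax = y[kplus = kminus = k = k0]) - twolambda;
      umin = lambda; umax = minlambda;
    } else { // no jump: extend the current segment
      ++k;
      if (umin >= lambda) {
        vmin += (umin - lambda) / ((kminus = k) - k0 + 1);
        umin = lambda;
      }
      if (umax <= minlambda) {
        vmax += (umax + lambda) / ((kplus = k) - k0 + 1);
        umax = minlambda;
      }
    }
  }
}

static inline double soft(const double v, const double t) {
  if (v > t) return v - t;
  if (v < -t) return v + t;
  return 0.0;
}

// prox of lambda1 ||.||_1 + lambda2 * TV applied per chain of length k:
// TV prox first, then elementwise soft-threshold (exact for chain graphs).
static void prox_chains(const arma::vec &z, arma::vec &out, const int k,
                        const double lambda1, const double lambda2) {
  const int p = z.n_elem, m = p / k;
  for (int t = 0; t < m; ++t)
    tv1d_condat(z.memptr() + t * k, out.memptr() + t * k, k, lambda2);
  if (lambda1 > 0.0)
    for (int j = 0; j < p; ++j) out[j] = soft(out[j], lambda1);
}

// [[Rcpp::export(name = ".prox_chain_cpp")]]
arma::vec prox_chain_cpp(const arma::vec &z, const double lambda1,
                         const double lambda2, const int k) {
  arma::vec out(z.n_elem);
  prox_chains(z, out, k, lambda1, lambda2);
  return out;
}

static double penalty_value(const arma::vec &beta, const int k,
                            const double lambda1, const double lambda2) {
  const int p = beta.n_elem, m = p / k;
  double pen = lambda1 * arma::accu(arma::abs(beta));
  for (int t = 0; t < m; ++t)
    for (int j = 1; j < k; ++j)
      pen += lambda2 * std::fabs(beta[t * k + j] - beta[t * k + j - 1]);
  return pen;
}

// FISTA with function-value restart on the Gram form of
//   ||y - X beta||^2 + lambda1 ||beta||_1 + lambda2 sum_chains TV(beta)
// where G = X'X, b = X'y, yty = y'y (X, y centered by the caller).
// L must satisfy L >= 2 * lambda_max(G).
// [[Rcpp::export(name = ".fista_fused_cpp")]]
Rcpp::List fista_fused_cpp(const arma::mat &G, const arma::vec &b,
                           const double yty, const int k,
                           const double lambda1, const double lambda2,
                           const arma::vec &beta_init, const double L,
                           const double tol, const int maxit) {
  const int p = G.n_rows;
  arma::vec beta = beta_init, theta = beta_init, beta_new(p), z(p), Gv(p);
  double tk = 1.0;
  Gv = G * beta;
  double obj_prev = yty - 2.0 * arma::dot(b, beta) + arma::dot(beta, Gv) +
                    penalty_value(beta, k, lambda1, lambda2);
  bool converged = false;
  int it = 0;
  const double step = 1.0 / L;
  for (it = 1; it <= maxit; ++it) {
    Gv = G * theta;
    z = theta - 2.0 * step * (Gv - b);
    prox_chains(z, beta_new, k, lambda1 * step, lambda2 * step);
    Gv = G * beta_new;
    double obj = yty - 2.0 * arma::dot(b, beta_new) + arma::dot(beta_new, Gv) +
                 penalty_value(beta_new, k, lambda1, lambda2);
    if (obj > obj_prev) { // momentum overshoot: restart from last iterate
      tk = 1.0;
      Gv = G * beta;
      z = beta - 2.0 * step * (Gv - b);
      prox_chains(z, beta_new, k, lambda1 * step, lambda2 * step);
      Gv = G * beta_new;
      obj = yty - 2.0 * arma::dot(b, beta_new) + arma::dot(beta_new, Gv) +
            penalty_value(beta_new, k, lambda1, lambda2);
    }
    const double tk1 = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
    theta = beta_new + ((tk - 1.0) / tk1) * (beta_new - beta);
    tk = tk1;
    const double rel =
        std::fabs(obj_prev - obj) / std::max(1.0, std::fabs(obj_prev));
    beta = beta_new;
    if (rel < tol) {
      converged = true;
      obj_prev = obj;
      break;
    }
    obj_prev = obj;
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("objective") = obj_prev,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = converged);
}
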