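// Neighborhood component analysis feature weighting.
//
// Distance model: d_w(x_i, x_j) = sum_r w_r^2 |x_ir - x_jr|.
// Reference probabilities: p_ij = exp(-d_ij / sigma) / sum_{l != i} exp(-d_il / sigma).
// Objective: xi(w) = sum_i p_i - lambda * sum_r w_r^2,  p_i = sum_{j != i, y_j = y_i} p_ij.
// Gradient: dxi/dw_r = (2 w_r / sigma) * sum_{i,j} p_ij (p_i - [y_i == y_j]) |x_ir - x_jr|
//           - 2 lambda w_r.
//
// Feature access is blocked over contiguous column ranges of the transposed
// (feature-major) matrix so the n^2/2 pair scan streams the data once per
// pass regardless of width.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const arma::uword BLOCK = 4096;

// Pairwise weighted-L1 distances; D is overwritten (n x n, symmetric).
static void pair_dist(const arma::mat &Xt, const arma::vec &w2, arma::mat &D) {
  const arma::uword p = Xt.n_rows, n = Xt.n_cols;
  D.zeros(n, n);
  for (arma::uword b0 = 0; b0 < p; b0 += BLOCK) {
    const arma::uword b1 = std::min(b0 + BLOCK, p);
    const arma::uword len = b1 - b0;
    const double *w2p = w2.memptr() + b0;
    for (arma::uword i = 0; i + 1 < n; ++i) {
      const double *xi = Xt.colptr(i) + b0;
      for (arma::uword j = i + 1; j < n; ++j) {
        const double *xj = Xt.colptr(j) + b0;
        // four independent accumulators so the reduction pipelines/vectorizes
        double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
        arma::uword r = 0;
        for (; r + 4 <= len; r += 4) {
          s0 += w2p[r] * std::fabs(xi[r] - xj[r]);
          s1 += w2p[r + 1] * std::fabs(xi[r + 1] - xj[r + 1]);
          s2 += w2p[r + 2] * std::fabs(xi[r + 2] - xj[r + 2]);
          s3 += w2p[r + 3] * std::fabs(xi[r + 3] - xj[r + 3]);
        }
        for (; r < len; ++r)
          s0 += w2p[r] * std::fabs(xi[r] - xj[r]);
        D(i, j) += (s0 + s1) + (s2 + s3);
      }
    }
  }
  D = arma::symmatu(D);
}

// Row-stochastic reference probabilities (max-shifted softmax of -D/sigma,
// diagonal excluded), per-sample same-class mass p_i, and the objective.
static double objective_parts(const arma::mat &D, const arma::ivec &y,
                              double sigma, double lambda, const arma::vec &w,
                              arma::mat &P, arma::vec &pi_same) {
  const arma::uword n = D.n_rows;
  P.zeros(n, n);
  pi_same.zeros(n);
  for (arma::uword i = 0; i < n; ++i) {
    double dmin = arma::datum::inf;
    for (arma::uword j = 0; j < n; ++j)
      if (j != i && D(i, j) < dmin) dmin = D(i, j);
    double z = 0.0;
    for (arma::uword j = 0; j < n; ++j) {
      if (j == i) continue;
      double e = std::exp(-(D(i, j) - dmin) / sigma);
      P(i, j) = e;
      z += e;
    }
    double s = 0.0;
    for (arma::uword j = 0; j < n; ++j) {
      if (j == i) continue;
      P(i, j) /= z;
      if (y[j] == y[i]) s += P(i, j);
    }
    pi_same[i] = s;
  }
  return arma::accu(pi_same) - lambda * arma::dot(w, w);
}

// Gradient accumulation: g_r = sum_{i<j} c_ij |x_ir - x_jr| with the
// symmetrized coefficient; returns dxi/dw.
static void gradient_pass(const arma::mat &Xt, const arma::mat &C,
                          const arma::vec &w, double lambda, arma::vec &grad) {
  const arma::uword p = Xt.n_rows, n = Xt.n_cols;
  arma::vec g(p, arma::fill::zeros);
  for (arma::uword b0 = 0; b0 < p; b0 += BLOCK) {
    const arma::uword b1 = std::min(b0 + BLOCK, p);
    const arma::uword len = b1 - b0;
    double *gp = g.memptr() + b0;
    for (arma::uword i = 0; i + 1 < n; ++i) {
      const double *xi = Xt.colptr(i) + b0;
      for (arma::uword j = i + 1; j < n; ++j) {
        const double c = C(i, j);
        if (c == 0.0) continue;
        const double *xj = Xt.colptr(j) + b0;
        for (arma::uword r = 0; r < len; ++r)
          gp[r] += c * std::fabs(xi[r] - xj[r]);
      }
    }
  }
  grad = 2.0 * (w % g) - 2.0 * lambda * w;
}

static arma::mat feature_major(const arma::mat &X, bool standardize) {
  arma::mat Xt = X.t(); // p x n
  if (standardize) {
    const arma::uword p = Xt.n_rows;
    for (arma::uword r = 0; r < p; ++r) {
      arma::rowvec row = Xt.row(r);
      double m = arma::mean(row);
      double s = arma::stddev(row); // n-1 denominator, matching R's sd()
      if (s > 0)
        Xt.row(r) = (row - m) / s;
      else
        Xt.row(r).zeros();
    }
  }
  return Xt;
}

static arma::mat coef_matrix(const arma::mat &P, const arma::vec &pi_same,
                             const arma::ivec &y, double sigma) {
  const arma::uword n = P.n_rows;
  arma::mat C(n, n, arma::fill::zeros);
  for (arma::uword i = 0; i + 1 < n; ++i)
    for (arma::uword j = i + 1; j < n; ++j) {
      const double s_ij = (y[i] == y[j]) ? 1.0 : 0.0;
      C(i, j) = (P(i, j) * (pi_same[i] - s_ij) +
                 P(j, i) * (pi_same[j] - s_ij)) / sigma;
    }
  return C;
}

// [[Rcpp::export]]
List nca_fit_cpp(const arma::mat &X, const arma::ivec &y, double sigma,
                 double lambda, double lr0, int max_iters, double tol,
                 bool standardize) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::mat Xt = feature_major(X, standardize);
  arma::vec w(p, arma::fill::ones);
  arma::mat D(n, n), P(n, n), C(n, n);
  arma::vec pi_same(n), grad(p), w2(p);

  w2 = arma::square(w);
  pair_dist(Xt, w2, D);
  double sigma_used = sigma;
  if (sigma_used <= 0) { // auto: mean off-diagonal initial distance
    double s = arma::accu(D) / (double)(n * (n - 1));
    sigma_used = (s > 0) ? s : 1.0;
  }
  double obj = objective_parts(D, y, sigma_used, lambda, w, P, pi_same);
  if (!std::isfinite(obj))
    stop("non-finite NCA objective at initialization");

  std::vector<double> trace;
  trace.push_back(obj);
  bool converged = false;
  double lr = lr0;
  int it = 0;
  for (it = 1; it <= max_iters; ++it) {
    C = coef_matrix(P, pi_same, y, sigma_used);
    gradient_pass(Xt, C, w, lambda, grad);
    // backtracking ascent: accept only non-decreasing steps
    bool accepted = false;
    double obj_try = obj;
    arma::vec w_try;
    for (int h = 0; h < 30; ++h) {
      w_try = w + lr * grad;
      w2 = arma::square(w_try);
      pair_dist(Xt, w2, D);
      obj_try = objective_parts(D, y, sigma_used, lambda, w_try, P, pi_same);
      if (!std::isfinite(obj_try))
        stop("non-finite NCA objective at iteration %d", it);
      if (obj_try >= obj - 1e-12) { accepted = true; break; }
      lr *= 0.5;
    }
    if (!accepted) { // objective cannot be improved along the gradient
      // restore P/pi_same consistency with current w before leaving
      w2 = arma::square(w);
      pair_dist(Xt, w2, D);
      objective_parts(D, y, sigma_used, lambda, w, P, pi_same);
      converged = true;
      break;
    }
    double rel = (obj_try - obj) / (std::fabs(obj) + 1e-12);
    w = w_try;
    obj = obj_try;
    trace.push_back(obj);
    lr *= 1.2;
    if (rel < tol) { converged = true; break; }
  }
  return List::create(_["weights"] = arma::abs(w),
                      _["objective_trace"] = trace,
                      _["converged"] = converged,
                      _["iterations"] = (int)trace.size() - 1,
                      _["sigma_used"] = sigma_used);
}

// Objective and analytic gradient at a given weight vector (no fitting);
// used for diagnostics and gradient verification.
// [[Rcpp::export]]
List nca_grad_cpp(const arma::mat &X, const arma::ivec &y, const arma::vec &w,
                  double sigma, double lambda, bool standardize) {
  const arma::uword n = X.n_rows;
  arma::mat Xt = feature_major(X, standardize);
  arma::mat D(n, n), P(n, n);
  arma::vec pi_same(n), grad;
  arma::vec w2 = arma::square(w);
  pair_dist(Xt, w2, D);
  double sigma_used = sigma;
  if (sigma_used <= 0) {
    double s = arma::accu(D) / (double)(n * (n - 1));
    sigma_used = (s > 0) ? s : 1.0;
  }
  double obj = objective_parts(D, y, sigma_used, lambda, w, P, pi_same);
  arma::mat C = coef_matrix(P, pi_same, y, sigma_used);
  gradient_pass(Xt, C, w, lambda, grad);
  return List::create(_["objective"] = obj, _["gradient"] = grad,
                      _["sigma_used"] = sigma_used);
}
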