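// Coordinate-descent SCAD path and LARS trajectory solvers.
//
// Both solvers expect a design whose columns have mean zero and mean
// square one (so that for each column (1/n) * x'x = 1) and a centered
// response; the R wrappers own the standardization and back-transform.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static inline double soft_threshold(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Minimizer of (1/2)(b - z)^2 + SCAD_{lambda,a}(|b|) for a unit-scaled
// coordinate: soft-thresholding below 2*lambda, a linearly interpolating
// middle piece up to a*lambda, and the unshrunken z beyond a*lambda.
static inline double scad_update(double z, double lambda, double a) {
  double az = std::fabs(z);
  if (az <= 2.0 * lambda) return soft_threshold(z, lambda);
  if (az <= a * lambda) {
    double shift = (z > 0 ? 1.0 : -1.0) * a * lambda / (a - 1.0);
    return (z - shift) / (1.0 - 1.0 / (a - 1.0));
  }
  return z;
}

// [[Rcpp::export(name = ".scad_update_cpp")]]
Rcpp::NumericVector scad_update_cpp(Rcpp::NumericVector z, double lambda, double a) {
  Rcpp::NumericVector out(z.size());
  for (R_xlen_t i = 0; i < z.size(); ++i) out[i] = scad_update(z[i], lambda, a);
  return out;
}

// SCAD path by cyclic coordinate descent with warm starts. X is n x p
// (standardized as above), y centered, lambda strictly decreasing.
// Convergence: max absolute coefficient change < tol. Non-convergence at
// a lambda is flagged, with the last iterate kept.
// [[Rcpp::export(name = ".scad_cd_path_cpp")]]
Rcpp::List scad_cd_path_cpp(const arma::mat& X, const arma::vec& y,
                            const arma::vec& lambda, double a,
                            int max_iter, double tol) {
  const arma::uword n = X.n_rows, p = X.n_cols, L = lambda.n_elem;
  arma::mat betas(p, L, arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);
  arma::vec resid = y;
  Rcpp::LogicalVector converged(L);
  Rcpp::IntegerVector iters(L);

  for (arma::uword l = 0; l < L; ++l) {
    const double lam = lambda(l);
    int it = 0;
    bool ok = false;
    bool full_sweep = true;  // alternate: full sweeps establish the active set
    arma::uvec active = arma::find(beta != 0.0);
    while (it < max_iter) {
      ++it;
      double max_change = 0.0;
      if (full_sweep) {
        for (arma::uword j = 0; j < p; ++j) {
          double bj = beta(j);
          double z = bj + arma::dot(X.col(j), resid) / n;
          double bn = scad_update(z, lam, a);
          if (bn != bj) {
            resid -= (bn - bj) * X.col(j);
            beta(j) = bn;
            double ch = std::fabs(bn - bj);
            if (ch > max_change) max_change = ch;
          }
        }
        active = arma::find(beta != 0.0);
      } else {
        for (arma::uword k = 0; k < active.n_elem; ++k) {
          const arma::uword j = active(k);
          double bj = beta(j);
          double z = bj + arma::dot(X.col(j), resid) / n;
          double bn = scad_update(z, lam, a);
          if (bn != bj) {
            resid -= (bn - bj) * X.col(j);
            beta(j) = bn;
            double ch = std::fabs(bn - bj);
            if (ch > max_change) max_change = ch;
          }
        }
      }
      if (max_change < tol) {
        if (full_sweep) { ok = true; break; }
        full_sweep = true;   // active set stable; confirm with a full sweep
      } else {
        full_sweep = false;  // iterate on the active set
      }
    }
    converged[l] = ok;
    iters[l] = it;
    betas.col(l) = beta;
  }
  return Rcpp::List::create(Rcpp::Named("betas") = betas,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("iters") = iters);
}

// LARS (least angle regression, no lasso modification). X standardized as
// above, y centered. Returns the piecewise-linear coefficient trajectory
// at its knots: betas is p x (nsteps + 1), first column all zero. A
// variable whose entry would make the active Gram matrix numerically
// singular is dropped (marked ineligible) with a count returned.
// [[Rcpp::export(name = ".lars_path_cpp")]]
Rcpp::List lars_path_cpp(const arma::mat& X, const arma::vec& y, int max_steps) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const arma::uword kmax = std::min<arma::uword>(max_steps, std::min<arma::uword>(n - 1, p));
  arma::vec resid = y;
  arma::mat R;                      // Cholesky (upper) of X_A' X_A
  std::vector<arma::uword> active;
  std::vector<bool> inactive(p, true);
  arma::mat betas(p, kmax + 1, arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);
  int dropped = 0;
  arma::uword step = 0;
  const double ctol = 1e-10 * std::sqrt(arma::dot(y, y) / n + 1e-300);

  while (active.size() < kmax) {
    arma::vec c = X.t() * resid;
    // entering variable: largest absolute correlation among eligible
    double cmax = -1.0; arma::sword jnew = -1;
    for (arma::uword j = 0; j < p; ++j) {
      if (inactive[j] && std::fabs(c(j)) > cmax) { cmax = std::fabs(c(j)); jnew = j; }
    }
    if (jnew < 0 || cmax < ctol) break;

    // Cholesky append for the entering column
    arma::vec xj = X.col((arma::uword)jnew);
    arma::uword k = active.size();
    arma::vec g(k);
    for (arma::uword i = 0; i < k; ++i) g(i) = arma::dot(X.col(active[i]), xj);
    double gjj = arma::dot(xj, xj);
    arma::vec rk;
    double d2;
    if (k == 0) {
      d2 = gjj;
      rk.set_size(0);
    } else {
      rk = arma::solve(arma::trimatl(R.t()), g);
      d2 = gjj - arma::dot(rk, rk);
    }
    if (d2 <= 1e-10 * gjj) {  // collinear with active set: drop it
      inactive[(arma::uword)jnew] = false;
      ++dropped;
      continue;
    }
    arma::mat Rn(k + 1, k + 1, arma::fill::zeros);
    if (k > 0) {
      Rn.submat(0, 0, k - 1, k - 1) = R;
      Rn.submat(0, k, k - 1, k) = rk;
    }
    Rn(k, k) = std::sqrt(d2);
    R = Rn;
    active.push_back((arma::uword)jnew);
    inactive[(arma::uword)jnew] = false;
    k = active.size();

    // equiangular direction
    c = X.t() * resid;
    arma::vec cA(k), s(k);
    for (arma::uword i = 0; i < k; ++i) {
      cA(i) = c(active[i]);
      s(i) = (cA(i) >= 0 ? 1.0 : -1.0);
    }
    cmax = arma::max(arma::abs(cA));
    arma::vec GA1 = arma::solve(arma::trimatu(R), arma::solve(arma::trimatl(R.t()), s));
    double AA = 1.0 / std::sqrt(arma::dot(s, GA1));
    arma::vec w = AA * GA1;
    arma::vec u(n, arma::fill::zeros);
    for (arma::uword i = 0; i < k; ++i) u += w(i) * X.col(active[i]);
    arma::vec aall = X.t() * u;

    // step length to the next entering variable (min over positive
    // candidates); a candidate already tied with cmax is excluded — its
    // ratios are 0/0 noise — and will be proposed as the next entrant
    double gamma = cmax / AA;  // full step to the active-set OLS fit
    if (active.size() < kmax) {
      for (arma::uword j = 0; j < p; ++j) {
        if (!inactive[j]) continue;
        if (std::fabs(c(j)) >= cmax * (1.0 - 1e-12)) continue;
        double d1 = (cmax - c(j)) / (AA - aall(j));
        double d2c = (cmax + c(j)) / (AA + aall(j));
        if (d1 > 1e-12 && d1 < gamma) gamma = d1;
        if (d2c > 1e-12 && d2c < gamma) gamma = d2c;
      }
    }
    for (arma::uword i = 0; i < k; ++i) beta(active[i]) += gamma * w(i);
    resid -= gamma * u;
    ++step;
    betas.col(step) = beta;
  }
  return Rcpp::List::create(Rcpp::Named("betas") = betas.cols(0, step),
                            Rcpp::Named("nsteps") = (int)step,
                            Rcpp::Named("active") = Rcpp::IntegerVector(active.begin(), active.end()),
                            Rcpp::Named("dropped") = dropped);
}
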