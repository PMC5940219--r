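// Weighted-lasso coordinate descent.
//
// Per-gene objective, with n = number of samples:
//   (1/(2n)) * ||y - X beta||^2 + lambda1 * sum_k delta_k * |beta_k|
// X columns are expected to be centered and (population-)standardized by
// the caller for full-data fits; cross-validation works on row subsets, so
// the updates handle arbitrary column norms.
//
// Two kernels are provided: a residual-update solver working directly on
// (X, y) for the exported single-gene API, and a covariance-update solver
// working on precomputed (X'X, X'y) that the whole-model fitting round
// uses (much cheaper when M << n and fits are sparse).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// ---------------------------------------------------------------- X-based

static double sweep_once(const arma::mat& X, arma::vec& r, arma::vec& beta,
                         const arma::vec& penalty, const arma::vec& xtx_n,
                         const arma::uvec& idx, double n) {
  double maxdel = 0.0;
  for (arma::uword ii = 0; ii < idx.n_elem; ++ii) {
    arma::uword k = idx[ii];
    if (xtx_n[k] <= 0.0) { beta[k] = 0.0; continue; }
    double bk = beta[k];
    double z = arma::dot(X.col(k), r) / n + xtx_n[k] * bk;
    double bnew = soft(z, penalty[k]) / xtx_n[k];
    if (bnew != bk) {
      r += X.col(k) * (bk - bnew);
      beta[k] = bnew;
      double d = std::abs(bnew - bk);
      if (d > maxdel) maxdel = d;
    }
  }
  return maxdel;
}

static int cd_core(const arma::mat& X, const arma::vec& y, arma::vec& beta,
                   const arma::vec& penalty, double tol, int max_sweeps,
                   bool& converged) {
  const double n = static_cast<double>(X.n_rows);
  arma::vec xtx_n = arma::sum(arma::square(X), 0).t() / n;
  arma::vec r = y - X * beta;
  arma::uvec all = arma::regspace<arma::uvec>(0, X.n_cols - 1);
  int sweeps = 0;
  converged = false;
  while (sweeps < max_sweeps) {
    double del = sweep_once(X, r, beta, penalty, xtx_n, all, n);
    ++sweeps;
    if (del < tol) { converged = true; break; }
    arma::uvec act = arma::find(beta != 0.0);
    while (act.n_elem > 0 && sweeps < max_sweeps) {
      double d2 = sweep_once(X, r, beta, penalty, xtx_n, act, n);
      ++sweeps;
      if (d2 < tol) break;
    }
  }
  return sweeps;
}

// [[Rcpp::export(name = ".cd_solve")]]
List cd_solve(const arma::mat& X, const arma::vec& y, const arma::vec& delta,
              double lambda1, const arma::vec& beta0, double tol,
              int max_sweeps) {
  arma::vec beta = beta0;
  arma::vec penalty = lambda1 * delta;
  bool conv = false;
  int sweeps = cd_core(X, y, beta, penalty, tol, max_sweeps, conv);
  return List::create(_["beta"] = beta, _["sweeps"] = sweeps,
                      _["converged"] = conv);
}

// Warm-started fits along a decreasing lambda path; returns M x L matrix.
// [[Rcpp::export(name = ".cd_path")]]
arma::mat cd_path(const arma::mat& X, const arma::vec& y,
                  const arma::vec& delta, const arma::vec& lambdas,
                  double tol, int max_sweeps) {
  const arma::uword M = X.n_cols, L = lambdas.n_elem;
  arma::mat out(M, L, arma::fill::zeros);
  arma::vec beta(M, arma::fill::zeros);
  bool conv = false;
  for (arma::uword l = 0; l < L; ++l) {
    arma::vec penalty = lambdas[l] * delta;
    cd_core(X, y, beta, penalty, tol, max_sweeps, conv);
    out.col(l) = beta;
  }
  return out;
}

// K-fold cross-validation errors for one gene over a lambda path.
// fold_ids are 1-based; returns mean held-out squared error per lambda.
// [[Rcpp::export(name = ".cd_cv")]]
arma::vec cd_cv(const arma::mat& X, const arma::vec& y,
                const arma::vec& delta, const arma::vec& lambdas,
                const arma::ivec& fold_ids, double tol, int max_sweeps) {
  const arma::uword L = lambdas.n_elem;
  const int K = fold_ids.max();
  arma::vec sse(L, arma::fill::zeros);
  for (int f = 1; f <= K; ++f) {
    arma::uvec test = arma::find(fold_ids == f);
    arma::uvec train = arma::find(fold_ids != f);
    arma::mat Xtr = X.rows(train), Xte = X.rows(test);
    arma::vec ytr = y.elem(train), yte = y.elem(test);
    arma::vec beta(X.n_cols, arma::fill::zeros);
    bool conv = false;
    for (arma::uword l = 0; l < L; ++l) {
      arma::vec penalty = lambdas[l] * delta;
      cd_core(Xtr, ytr, beta, penalty, tol, max_sweeps, conv);
      arma::vec resid = yte - Xte * beta;
      sse[l] += arma::dot(resid, resid);
    }
  }
  return sse / static_cast<double>(X.n_rows);
}

// ------------------------------------------------------------ covariance

// Coordinate descent on precomputed Gram quantities.  q = XtX * beta is
// maintained incrementally, so a coordinate visit is O(1) plus O(M) when
// the coefficient actually changes.
static int cd_cov_core(const arma::mat& XtX, const arma::vec& Xty,
                       arma::vec& beta, arma::vec& q,
                       const arma::vec& penalty, double n, double tol,
                       int max_sweeps) {
  const arma::uword M = XtX.n_cols;
  int sweeps = 0;
  bool full = true;
  arma::uvec act;
  while (sweeps < max_sweeps) {
    double maxdel = 0.0;
    if (full) {
      for (arma::uword k = 0; k < M; ++k) {
        double d = XtX(k, k) / n;
        if (d <= 0.0) { beta[k] = 0.0; continue; }
        double bk = beta[k];
        double z = (Xty[k] - q[k]) / n + d * bk;
        double bnew = soft(z, penalty[k]) / d;
        if (bnew != bk) {
          q += XtX.col(k) * (bnew - bk);
          beta[k] = bnew;
          double ad = std::abs(bnew - bk);
          if (ad > maxdel) maxdel = ad;
        }
      }
    } else {
      for (arma::uword ii = 0; ii < act.n_elem; ++ii) {
        arma::uword k = act[ii];
        double d = XtX(k, k) / n;
        if (d <= 0.0) { beta[k] = 0.0; continue; }
        double bk = beta[k];
        double z = (Xty[k] - q[k]) / n + d * bk;
        double bnew = soft(z, penalty[k]) / d;
        if (bnew != bk) {
          q += XtX.col(k) * (bnew - bk);
          beta[k] = bnew;
          double ad = std::abs(bnew - bk);
          if (ad > maxdel) maxdel = ad;
        }
      }
    }
    ++sweeps;
    if (maxdel < tol) {
      if (full) return sweeps;   // converged on a full sweep
      full = true;               // active set stable; confirm with full sweep
    } else if (full) {
      act = arma::find(beta != 0.0);
      full = act.n_elem == 0;
    }
  }
  return sweeps;
}

static arma::vec log_spaced(double lmax, double ratio, int L) {
  arma::vec out(L);
  double llo = std::log(lmax * ratio), lhi = std::log(lmax);
  for (int i = 0; i < L; ++i)
    out[i] = std::exp(lhi + (llo - lhi) * i / (L - 1.0));
  return out;
}

// One whole-model fitting round: optional per-gene CV selection of
// lambda1 along a log-spaced path anchored at the per-gene null threshold,
// then warm-started full-data fits for every gene.
// [[Rcpp::export(name = ".fit_round")]]
List fit_round(const arma::mat& X, const arma::mat& Y,
               const arma::vec& delta, const arma::ivec& fold_ids,
               int n_lambda, double lambda_min_ratio, double tol,
               int max_sweeps, const arma::mat& beta_warm, bool do_cv,
               const arma::vec& lambda1_in, double cv_tol,
               int cv_max_sweeps) {
  const arma::uword n = X.n_rows, M = X.n_cols, G = Y.n_cols;
  const double nd = static_cast<double>(n);
  arma::mat XtX = X.t() * X;
  arma::mat XtY = X.t() * Y;
  arma::vec lambda1 = lambda1_in;

  if (do_cv) {
    const int K = fold_ids.max();
    std::vector<arma::mat> XtX_tr(K), XtX_te(K), XtY_te(K);
    std::vector<arma::mat> Yte(K);
    std::vector<arma::uvec> test(K);
    std::vector<double> ntr(K);
    for (int f = 0; f < K; ++f) {
      test[f] = arma::find(fold_ids == f + 1);
      arma::mat Xte = X.rows(test[f]);
      XtX_te[f] = Xte.t() * Xte;
      XtX_tr[f] = XtX - XtX_te[f];
      Yte[f] = Y.rows(test[f]);
      XtY_te[f] = Xte.t() * Yte[f];
      ntr[f] = nd - static_cast<double>(test[f].n_elem);
    }
    lambda1.set_size(G);
    for (arma::uword j = 0; j < G; ++j) {
      arma::vec xty = XtY.col(j);
      double lmax = arma::max(arma::abs(xty) / (nd * delta));
      if (!std::isfinite(lmax) || lmax <= 0.0) lmax = 1e-3;
      arma::vec grid = log_spaced(lmax, lambda_min_ratio, n_lambda);
      arma::vec err(n_lambda, arma::fill::zeros);
      for (int f = 0; f < K; ++f) {
        arma::vec xty_tr = xty - XtY_te[f].col(j);
        arma::vec yte = Yte[f].col(j);
        double yte2 = arma::dot(yte, yte);
        arma::vec xtyte = XtY_te[f].col(j);
        arma::vec beta(M, arma::fill::zeros);
        arma::vec q(M, arma::fill::zeros);
        arma::vec pen(M);
        for (int l = 0; l < n_lambda; ++l) {
          pen = grid[l] * delta;
          cd_cov_core(XtX_tr[f], xty_tr, beta, q, pen, ntr[f], cv_tol,
                      cv_max_sweeps);
          // held-out SSE = ||yte||^2 - 2 b'Xte'yte + b'(Xte'Xte)b
          double sse = yte2;
          if (arma::any(beta != 0.0))
            sse += -2.0 * arma::dot(beta, xtyte) +
              arma::dot(beta, XtX_te[f] * beta);
          err[l] += sse;
        }
      }
      // decreasing grid: first minimum = largest (sparsest) lambda
      arma::uword best = 0;
      double bestv = err[0];
      for (int l = 1; l < n_lambda; ++l)
        if (err[l] < bestv - 0.0) { bestv = err[l]; best = l; }
      lambda1[j] = grid[best];
    }
  }

  arma::mat beta_out(M, G);
  arma::ivec sweeps(G);
  for (arma::uword j = 0; j < G; ++j) {
    arma::vec beta = beta_warm.col(j);
    arma::vec q = XtX * beta;
    arma::vec pen = lambda1[j] * delta;
    sweeps[j] = cd_cov_core(XtX, XtY.col(j), beta, q, pen, nd, tol,
                            max_sweeps);
    beta_out.col(j) = beta;
  }
  return List::create(_["beta"] = beta_out, _["lambda1"] = lambda1,
                      _["sweeps"] = sweeps);
}
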