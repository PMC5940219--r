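#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - gamma, 0)`, the proximal map of the absolute value;
#' the elementary kernel of lasso coordinate descent.
#'
#' @param z Numeric vector.
#' @param gamma Non-negative threshold.
#' @return Numeric vector of the same length as `z`.
#' @export
soft_threshold <- function(z, gamma) {
  if (any(gamma < 0)) stop("gamma must be non-negative")
  sign(z) * pmax(abs(z) - gamma, 0)
}

#' Per-mutation penalty scale from weighted functional impact scores
#'
#' Maps each mutant allele's weighted functional-impact-score sum through a
#' sigmoid to a multiplicative scale on its L1 penalty.  In the default
#' `"oriented"` mode the features are impact-oriented (larger = more
#' damaging) and the sigmoid is applied to the negated sum, so high-impact
#' alleles receive *smaller* penalties and are easier to select.  The
#' `"literal"` mode applies the sigmoid to the raw weighted sum (larger
#' impact = larger penalty); it is exposed for comparison.  With `w = 0`
#' both modes give the uniform prior `delta = 0.5`.
#'
#' @param w Non-negative numeric vector of feature weights (one per
#'   feature).
#' @param F Numeric matrix, alleles x features (standardized,
#'   impact-oriented; see [build_feature_table()]).
#' @param mode `"oriented"` (default) or `"literal"`.
#' @param delta_min Lower clip for the scale (default 0.05); prevents a
#'   single allele with near-zero penalty from absorbing every gene.
#' @return Numeric vector of penalty scales in `[delta_min, 1)`, one per
#'   allele.
#' @export
penalty_scale <- function(w, F, mode = c("oriented", "literal"),
                          delta_min = 0.05) {
  mode <- match.arg(mode)
  F <- as.matrix(F)
  if (length(w) != ncol(F))
    stop("length(w) = ", length(w), " but F has ", ncol(F), " features")
  if (any(w < 0)) stop("feature weights must be non-negative")
  s <- drop(F %*% w)
  d <- if (mode == "oriented") stats::plogis(-s) else stats::plogis(s)
  pmin(pmax(d, delta_min), 1 - 1e-10)
}

#' Fit a weighted lasso for one gene by coordinate descent
#'
#' Minimizes, over beta,
#' \deqn{\frac{1}{2n}\|y - X\beta\|^2 + \lambda_1 \sum_k \delta_k |\beta_k|}
#' by cyclic coordinate descent with an active-set strategy.  `X` columns
#' should be centered and standardized and `y` centered (the model carries
#' no intercept).
#'
#' @param y Centered numeric response vector (one gene's expression).
#' @param X Standardized design matrix, samples x alleles.
#' @param delta Per-allele penalty scales (see [penalty_scale()]).
#' @param lambda1 Non-negative regularization strength.
#' @param beta0 Optional warm-start coefficients (default all zero).
#' @param tol Convergence tolerance on the maximum coefficient change per
#'   sweep (default 1e-6).
#' @param max_sweeps Sweep cap (default 1000); hitting it raises a warning
#'   and returns the best iterate.
#' @return Numeric coefficient vector with attributes `sweeps` and
#'   `converged`.
#' @export
fit_weighted_lasso <- function(y, X, delta, lambda1, beta0 = NULL,
                               tol = 1e-6, max_sweeps = 1000) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in X or y")
  if (length(delta) != ncol(X))
    stop("delta must have one entry per column of X")
  if (lambda1 < 0) stop("lambda1 must be non-negative")
  if (is.null(beta0)) beta0 <- numeric(ncol(X))
  res <- .cd_solve(X, y, as.numeric(delta), lambda1, as.numeric(beta0),
                   tol, as.integer(max_sweeps))
  beta <- drop(res$beta)
  names(beta) <- colnames(X)
  if (!res$converged)
    warning("coordinate descent did not converge in ", max_sweeps, " sweeps")
  attr(beta, "sweeps") <- res$sweeps
  attr(beta, "converged") <- res$converged
  beta
}

#' Penalized objective of the full model
#'
#' Evaluates, summed over genes j,
#' \deqn{\frac{1}{2n}\|y_j - X\beta_j\|^2 +
#'   \lambda_{1j}\sum_k \delta_k|\beta_{jk}| + \lambda_{2j}\sum_i w_i^2.}
#' The residual term uses the 1/(2n) convention so lambda grids do not
#' depend on sample size.
#'
#' @param Y Centered expression matrix, samples x genes.
#' @param X Standardized mutation matrix, samples x alleles.
#' @param beta Coefficient matrix, alleles x genes.
#' @param delta Per-allele penalty scales.
#' @param lambda1 Per-gene L1 strengths (recycled if scalar).
#' @param lambda2 Per-gene ridge strengths on the feature weights
#'   (recycled if scalar).
#' @param w Feature weight vector (may be length 0 when no impact scores
#'   are used).
#' @return Scalar objective value.
#' @export
model_objective <- function(Y, X, beta, delta, lambda1, lambda2,
                            w = numeric(0)) {
  Y <- as.matrix(Y); X <- as.matrix(X); beta <- as.matrix(beta)
  n <- nrow(Y)
  stopifnot(nrow(X) == n, ncol(X) == nrow(beta), ncol(beta) == ncol(Y))
  lambda1 <- rep_len(lambda1, ncol(Y))
  lambda2 <- rep_len(lambda2, ncol(Y))
  R <- Y - X %*% beta
  rss <- colSums(R^2) / (2 * n)
  l1 <- lambda1 * colSums(abs(beta) * delta)
  l2 <- lambda2 * sum(w^2)
  sum(rss + l1 + l2)
}

#' Select regularization strengths by k-fold cross-validation
#'
#' For one gene, evaluates mean held-out squared error over a decreasing
#' `lambda1` path (warm-started coordinate descent within each fold) and
#' returns the pair minimizing it (minimum rule; no one-standard-error
#' rule).  The default path has 20 log-spaced points from
#' `lambda_max = max_k |x_k' y| / (n delta_k)` (the smallest value that
#' zeroes all coefficients) down to `0.01 * lambda_max`.  Held-out
#' prediction error does not depend on `lambda2` (which penalizes only the
#' shared feature weights), so ties across `lambda2` are broken toward the
#' largest grid value (the most conservative prior influence); ties across
#' `lambda1` toward the largest (sparsest fit).
#'
#' @param y Centered response vector.
#' @param X Standardized design matrix.
#' @param delta Per-allele penalty scales.
#' @param lambda1_grid Optional decreasing grid; computed from the data if
#'   `NULL`.
#' @param lambda2_grid Candidate ridge strengths (default `c(0.01, 0.1, 1)`).
#' @param k_folds Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @param n_lambda,lambda_min_ratio Path size and ratio used when
#'   `lambda1_grid` is `NULL`.
#' @param tol,max_sweeps Passed to the coordinate-descent solver.
#' @return List with `lambda1`, `lambda2`, the evaluated `lambda1_grid`,
#'   `cv_error` per grid point and the fold assignment `folds`.
#' @export
select_lambdas_cv <- function(y, X, delta, lambda1_grid = NULL,
                              lambda2_grid = c(0.01, 0.1, 1), k_folds = 10,
                              seed = 1, n_lambda = 20,
                              lambda_min_ratio = 0.01, tol = 1e-6,
                              max_sweeps = 1000) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k_folds)
    stop("n = ", n, " < k_folds = ", k_folds,
         "; use fewer folds")
  if (is.null(lambda1_grid))
    lambda1_grid <- lambda_path(y, X, delta, n_lambda, lambda_min_ratio)
  folds <- cv_folds(n, k_folds, seed)
  err <- drop(.cd_cv(X, y, as.numeric(delta), as.numeric(lambda1_grid),
                     as.integer(folds), tol, as.integer(max_sweeps)))
  best <- which.min(err)  # grid is decreasing: first minimum = largest lambda
  list(lambda1 = lambda1_grid[best], lambda2 = max(lambda2_grid),
       lambda1_grid = lambda1_grid, cv_error = err, folds = folds)
}

# Decreasing log-spaced lambda1 path anchored at the null threshold.
lambda_path <- function(y, X, delta, n_lambda = 20, lambda_min_ratio = 0.01) {
  n <- nrow(X)
  lmax <- max(abs(crossprod(X, y)) / (n * delta))
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

# Deterministic fold assignment from a seeded shuffle.
cv_folds <- function(n, k, seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Update feature weights by projected gradient descent
#'
#' Given fixed coefficients, minimizes
#' \deqn{\sum_j \lambda_{1j} \sum_k \delta_k(w) |\beta_{jk}| +
#'   \Big(\sum_j \lambda_{2j}\Big) \sum_i w_i^2}
#' over `w >= 0`, where `delta_k(w)` is the sigmoid penalty scale of
#' [penalty_scale()].  Uses backtracking (Armijo) line search, so the
#' objective never increases; intermediate negative coordinates are
#' projected to zero.
#'
#' @param beta Coefficient matrix, alleles x genes.
#' @param F Standardized impact-oriented feature matrix, alleles x features.
#' @param lambda1 Per-gene L1 strengths.
#' @param lambda2 Per-gene ridge strengths.
#' @param w Starting weights (non-negative).
#' @param mode Penalty-scale mode, `"oriented"` or `"literal"`.
#' @param delta_min Lower clip for the penalty scale.
#' @param maxit Iteration cap (default 200).
#' @param tol Stop when the projected-gradient norm falls below this
#'   (default 1e-6).
#' @return Non-negative weight vector with attribute `converged`.
#' @export
update_weights <- function(beta, F, lambda1, lambda2, w,
                           mode = c("oriented", "literal"),
                           delta_min = 0.05, maxit = 200, tol = 1e-6) {
  mode <- match.arg(mode)
  F <- as.matrix(F); beta <- as.matrix(beta)
  if (any(w < 0)) stop("starting weights must be non-negative")
  lambda1 <- rep_len(lambda1, ncol(beta))
  ck <- drop(abs(beta) %*% lambda1)        # per-allele L1 mass
  R <- sum(rep_len(lambda2, ncol(beta)))   # total ridge strength
  sgn <- if (mode == "oriented") -1 else 1

  hval <- function(w) {
    d <- pmin(pmax(stats::plogis(sgn * drop(F %*% w)), delta_min), 1 - 1e-10)
    sum(ck * d) + R * sum(w^2)
  }
  hgrad <- function(w) {
    s <- sgn * drop(F %*% w)
    d <- stats::plogis(s)
    live <- d > delta_min & d < 1 - 1e-10   # clipped region has zero slope
    dd <- ifelse(live, d * (1 - d), 0)
    drop(crossprod(F, ck * dd * sgn)) + 2 * R * w
  }

  h <- hval(w)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    g <- hgrad(w)
    pg <- w - pmax(w - g, 0)
    if (sqrt(sum(pg^2)) < tol) { converged <- TRUE; break }
    step <- 1
    repeat {
      wn <- pmax(w - step * g, 0)
      hn <- hval(wn)
      if (hn <= h - 1e-4 * sum((w - wn)^2) / max(step, 1e-12)) break
      step <- step / 2
      if (step < 1e-14) { wn <- w; hn <- h; break }
    }
    if (identical(wn, w)) { converged <- sqrt(sum(pg^2)) < tol; break }
    w <- wn; h <- hn
  }
  structure(w, converged = converged)
}
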