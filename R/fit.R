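#' Control parameters for the driver-mutation association model
#'
#' @param delta_mode How functional impact scores enter the per-mutation
#'   penalty scale: `"oriented"` (default; high-impact alleles penalized
#'   less), `"literal"` (sigmoid of the raw weighted sum) or `"none"`
#'   (prior-free, scale fixed at 1; also used when no features are given).
#' @param delta_min Lower clip for the penalty scale (default 0.05).
#' @param n_lambda Number of points on the per-gene lambda1 path
#'   (default 20).
#' @param lambda_min_ratio Smallest path point as a fraction of the
#'   per-gene null threshold `lambda_max` (default 0.01).
#' @param lambda2_grid Candidate ridge strengths on the feature weights
#'   (default `c(0.01, 0.1, 1)`).
#' @param k_folds Cross-validation folds for lambda selection (default 10).
#' @param tol_inner Coordinate-descent tolerance for the full-data fits
#'   (default 1e-8, tight enough that the stationarity conditions hold to
#'   about 1e-6).
#' @param max_sweeps Coordinate-descent sweep cap for the full-data fits
#'   (default 1000).
#' @param tol_cv,max_sweeps_cv Looser tolerance (1e-3) and sweep cap (50)
#'   for the fold fits inside cross-validation; lambda selection is an
#'   argmin over a coarse grid and is insensitive to the extra precision,
#'   which the full-data fits restore.
#' @param max_outer Cap on outer alternations between coefficient fits and
#'   weight updates (default 20).
#' @param tol_outer Relative objective change below which the outer loop
#'   stops (default 1e-4).
#' @return List of class `"exdriver_control"`.
#' @export
exdriver_control <- function(delta_mode = c("oriented", "literal", "none"),
                             delta_min = 0.05, n_lambda = 20,
                             lambda_min_ratio = 0.01,
                             lambda2_grid = c(0.01, 0.1, 1), k_folds = 10,
                             tol_inner = 1e-8, max_sweeps = 1000,
                             tol_cv = 1e-3, max_sweeps_cv = 50,
                             max_outer = 20, tol_outer = 1e-4) {
  structure(list(delta_mode = match.arg(delta_mode), delta_min = delta_min,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 lambda2_grid = lambda2_grid, k_folds = k_folds,
                 tol_inner = tol_inner, max_sweeps = max_sweeps,
                 tol_cv = tol_cv, max_sweeps_cv = max_sweeps_cv,
                 max_outer = max_outer, tol_outer = tol_outer),
            class = "exdriver_control")
}

#' Fit the expression-association driver-mutation model
#'
#' Regresses every gene's expression on the binary mutation design with a
#' per-mutation adaptive L1 penalty.  Each allele k carries a penalty scale
#' `delta_k = sigmoid(-sum_i w_i f_ki)` derived from its functional impact
#' scores, so alleles predicted to be damaging are easier to select.  The
#' fit alternates, starting from the uniform prior `w = 0`
#' (`delta = 0.5`):
#' (a) per-gene selection of `lambda1` by k-fold cross-validation given the
#' current scales, (b) per-gene weighted-lasso coordinate descent, and
#' (c) a projected-gradient update of the shared feature weights, until the
#' relative objective change falls below `tol_outer`.
#'
#' @param expression Numeric matrix, samples x genes (preprocessed scale;
#'   see [preprocess_expression()]).  Each gene is centered internally; the
#'   model has no intercept.
#' @param mutations Binary matrix, samples x alleles (see
#'   [build_mutation_matrix()]).  Columns are standardized internally
#'   (population convention).
#' @param features Optional matrix, alleles x features, of standardized
#'   impact-oriented functional impact scores (see
#'   [build_feature_table()]).  `NULL` fits the prior-free model.
#' @param control List from [exdriver_control()].
#' @param seed Integer seed; all internal randomness (cross-validation
#'   folds) derives from it.
#' @return Object of class `"exdriver"`: a list with the coefficient matrix
#'   `beta` (alleles x genes), feature `weights`, penalty scales `delta`,
#'   per-gene `lambda1`/`lambda2`, `objective_trace` (with one entry after
#'   each coefficient step and each weight step), per-gene `r2`, residual
#'   standard deviations `sigma`, convergence flag and the standardized
#'   training data.
#' @export
exdriver <- function(expression, mutations, features = NULL,
                     control = exdriver_control(), seed = 1) {
  Y <- as.matrix(expression)
  Xraw <- as.matrix(mutations)
  if (is.null(rownames(Y)) || is.null(rownames(Xraw)) ||
      !identical(rownames(Y), rownames(Xraw))) {
    if (!is.null(rownames(Y)) && !is.null(rownames(Xraw))) {
      al <- align_samples(Y, Xraw)
      Y <- al$expression; Xraw <- al$mutations
    } else if (nrow(Y) != nrow(Xraw)) {
      stop("expression and mutations must share samples")
    }
  }
  if (ncol(Xraw) < 1 || ncol(Y) < 1) stop("need at least one gene and allele")

  # drop degenerate columns rather than failing
  gvar <- apply(Y, 2, function(v) stats::var(v))
  if (any(gvar == 0)) {
    warning("dropping ", sum(gvar == 0), " constant gene(s)")
    Y <- Y[, gvar > 0, drop = FALSE]
  }
  avar <- apply(Xraw, 2, function(v) stats::var(v))
  if (any(avar == 0)) {
    warning("dropping ", sum(avar == 0), " constant mutation column(s)")
    Xraw <- Xraw[, avar > 0, drop = FALSE]
  }
  if (ncol(Xraw) == 0 || ncol(Y) == 0)
    stop("no informative columns left after dropping degenerate ones")

  n <- nrow(Y); G <- ncol(Y); M <- ncol(Xraw)
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (!is.null(rownames(features)))
      features <- features[colnames(Xraw), , drop = FALSE]
    if (nrow(features) != M)
      stop("features must have one row per mutation allele")
  }
  delta_mode <- control$delta_mode
  if (is.null(features) || ncol(features) == 0) delta_mode <- "none"

  xc <- colMeans(Xraw)
  xs <- sqrt(colMeans(Xraw^2) - xc^2)   # population sd; >0 after filtering
  X <- sweep(sweep(Xraw, 2, xc), 2, xs, "/")
  yc <- colMeans(Y)
  Yc <- sweep(Y, 2, yc)

  nF <- if (delta_mode == "none") 0L else ncol(features)
  w <- numeric(nF)
  delta <- if (delta_mode == "none") rep(1, M) else rep(0.5, M)
  lambda2 <- rep(max(control$lambda2_grid), G)
  cv_seed <- substream_seed(seed, "cv")
  folds_seed <- cv_seed

  beta <- matrix(0, M, G, dimnames = list(colnames(Xraw), colnames(Y)))
  lambda1 <- numeric(G)
  trace <- numeric(0)
  trace_step <- character(0)
  prev_obj <- Inf
  converged <- FALSE
  prev_delta <- rep(NA_real_, M)

  folds <- cv_folds(n, control$k_folds, folds_seed)

  for (it in seq_len(control$max_outer)) {
    # (a) per-gene lambda1 by CV given current delta (skipped when delta is
    # unchanged: the selection would repeat exactly), then (b) warm-started
    # per-gene weighted-lasso fits -- one whole-model round in C++
    do_cv <- it == 1 || max(abs(delta - prev_delta)) > 1e-10
    prev_delta <- delta
    rnd <- .fit_round(X, Yc, delta, as.integer(folds),
                      as.integer(control$n_lambda),
                      control$lambda_min_ratio, control$tol_inner,
                      as.integer(control$max_sweeps), beta, do_cv, lambda1,
                      control$tol_cv, as.integer(control$max_sweeps_cv))
    beta[, ] <- rnd$beta
    lambda1 <- drop(rnd$lambda1)
    obj_b <- model_objective(Yc, X, beta, delta, lambda1, lambda2, w)
    trace <- c(trace, obj_b); trace_step <- c(trace_step, "beta")

    # (c) feature-weight update (descent step on the same objective)
    if (delta_mode != "none") {
      w <- update_weights(beta, features, lambda1, lambda2, w,
                          mode = delta_mode, delta_min = control$delta_min)
      delta <- penalty_scale(w, features, mode = delta_mode,
                             delta_min = control$delta_min)
    }
    obj_w <- model_objective(Yc, X, beta, delta, lambda1, lambda2, w)
    trace <- c(trace, obj_w); trace_step <- c(trace_step, "weights")

    if (is.finite(prev_obj) &&
        abs(prev_obj - obj_w) <= control$tol_outer * max(1, abs(prev_obj))) {
      converged <- TRUE
      break
    }
    prev_obj <- obj_w
  }

  # the last weight step moved delta after the coefficients were fitted;
  # refit once at the final scales so beta, lambda1 and delta are mutually
  # consistent (and satisfy the stationarity conditions together)
  if (delta_mode != "none" && max(abs(delta - prev_delta)) > 1e-10) {
    do_cv <- TRUE
    rnd <- .fit_round(X, Yc, delta, as.integer(folds),
                      as.integer(control$n_lambda),
                      control$lambda_min_ratio, control$tol_inner,
                      as.integer(control$max_sweeps), beta, do_cv, lambda1,
                      control$tol_cv, as.integer(control$max_sweeps_cv))
    beta[, ] <- rnd$beta
    lambda1 <- drop(rnd$lambda1)
    obj_b <- model_objective(Yc, X, beta, delta, lambda1, lambda2, w)
    trace <- c(trace, obj_b); trace_step <- c(trace_step, "beta")
  }

  fitted_c <- X %*% beta
  rss <- colSums((Yc - fitted_c)^2)
  tss <- colSums(Yc^2)
  r2 <- ifelse(tss > 0, pmax(0, 1 - rss / tss), NA_real_)
  sigma <- sqrt(rss / n)

  structure(list(
    beta = beta,
    weights = setNames(w, if (nF) colnames(features) else NULL),
    delta = setNames(delta, colnames(Xraw)),
    lambda1 = setNames(lambda1, colnames(Y)),
    lambda2 = setNames(lambda2, colnames(Y)),
    objective_trace = setNames(trace, trace_step),
    r2 = setNames(as.numeric(r2), colnames(Y)),
    sigma = setNames(sigma, colnames(Y)),
    converged = converged,
    iterations = sum(trace_step == "weights"),
    X = X, X_raw = Xraw, Y = Y, y_center = yc,
    x_center = xc, x_scale = xs,
    features = if (delta_mode == "none") NULL else features,
    allele_meta = attr(mutations, "allele_meta"),
    control = control, delta_mode = delta_mode, seed = seed,
    n = n), class = "exdriver")
}

#' Per-gene variance explained by the fitted mutation effects
#'
#' `R2_j = 1 - ||y_j - X beta_j||^2 / ||y_j - mean(y_j)||^2`, computed
#' in-sample on the training data.  Zero-variance genes are reported as
#' `NA`.
#'
#' @param object Fitted `"exdriver"` model.
#' @return Named numeric vector of per-gene R-squared values in `[0, 1]`.
#' @export
variance_explained <- function(object) {
  stopifnot(inherits(object, "exdriver"))
  object$r2
}

#' @export
print.exdriver <- function(x, ...) {
  cat("Expression-association driver mutation model\n")
  cat(sprintf("  samples: %d   genes: %d   alleles: %d\n",
              x$n, ncol(x$beta), nrow(x$beta)))
  cat(sprintf("  penalty mode: %s   outer iterations: %d (%s)\n",
              x$delta_mode, x$iterations,
              if (x$converged) "converged" else "iteration cap reached"))
  cat(sprintf("  nonzero associations: %d (%.2f%% of %d)\n",
              sum(x$beta != 0), 100 * mean(x$beta != 0), length(x$beta)))
  cat(sprintf("  mean variance explained: %.1f%%\n",
              100 * mean(x$r2, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.exdriver <- function(object, n_top = 10, ...) {
  sc <- driver_scores(object)
  top <- sort(sc, decreasing = TRUE)
  top <- top[seq_len(min(n_top, length(top)))]
  out <- list(n = object$n, n_genes = ncol(object$beta),
              n_alleles = nrow(object$beta),
              mean_r2 = mean(object$r2, na.rm = TRUE),
              density = mean(object$beta != 0),
              weights = object$weights, top_alleles = top,
              converged = object$converged)
  class(out) <- "summary.exdriver"
  out
}

#' @export
print.summary.exdriver <- function(x, ...) {
  cat(sprintf(
    "Driver model: %d samples, %d genes, %d alleles; mean R2 = %.3f\n",
    x$n, x$n_genes, x$n_alleles, x$mean_r2))
  if (length(x$weights)) {
    cat("Feature weights:\n")
    print(round(x$weights, 4))
  }
  cat("Top alleles by driver score (number of associated genes):\n")
  print(x$top_alleles)
  invisible(x)
}

#' @export
coef.exdriver <- function(object, ...) object$beta

#' Predict gene expression from mutation profiles
#'
#' @param object Fitted `"exdriver"` model.
#' @param newdata Optional binary mutation matrix (samples x alleles, same
#'   alleles as training); defaults to the training data.
#' @param ... Unused.
#' @return Matrix of predicted expression, samples x genes (on the scale of
#'   the training expression, gene means added back).
#' @export
predict.exdriver <- function(object, newdata = NULL, ...) {
  Xn <- if (is.null(newdata)) object$X else {
    nd <- as.matrix(newdata)
    if (!is.null(colnames(nd))) nd <- nd[, rownames(object$beta), drop = FALSE]
    sweep(sweep(nd, 2, object$x_center), 2, object$x_scale, "/")
  }
  sweep(Xn %*% object$beta, 2, object$y_center, "+")
}

#' @export
fitted.exdriver <- function(object, ...) predict(object)

#' @export
residuals.exdriver <- function(object, ...) object$Y - predict(object)

#' Simulate expression matrices from a fitted driver model
#'
#' Draws `nsim` replicate expression matrices from the fitted linear model
#' `Y = X beta + eps`, with independent Gaussian noise at each gene's
#' estimated residual standard deviation.
#'
#' @param object Fitted `"exdriver"` model.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of `nsim` samples x genes matrices.
#' @export
simulate.exdriver <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  lapply(seq_len(nsim), function(i) {
    mu + matrix(rnorm(length(mu), sd = rep(object$sigma, each = nrow(mu))),
                nrow(mu), ncol(mu), dimnames = dimnames(mu))
  })
}

#' Diagnostic plots for a fitted driver model
#'
#' Left: penalized objective across the alternating steps (coefficient
#' fits and feature-weight updates).  Right: histogram of per-gene
#' variance explained.
#'
#' @param x Fitted `"exdriver"` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.exdriver <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(seq_along(x$objective_trace), x$objective_trace, type = "b",
       xlab = "alternating step", ylab = "penalized objective",
       main = "Objective trace", ...)
  hist(x$r2, breaks = 20, xlab = expression(R^2), main = "Variance explained")
  invisible(x)
}
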