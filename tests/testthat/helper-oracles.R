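# Independent oracles used to validate the package's own implementations.
# These deliberately use different algorithms from the code under test.

# Proximal-gradient (ISTA) solver for the weighted lasso
#   (1/(2n)) ||y - X b||^2 + lambda1 * sum delta_k |b_k|
# run to a very tight fixed-point tolerance.
prox_lasso_oracle <- function(y, X, delta, lambda1, tol = 1e-12,
                              max_iter = 5e5) {
  n <- nrow(X)
  L <- max(eigen(crossprod(X) / n, symmetric = TRUE,
                 only.values = TRUE)$values)
  step <- 1 / L
  b <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    g <- -drop(crossprod(X, y - X %*% b)) / n
    bn <- sign(b - step * g) * pmax(abs(b - step * g) -
                                      step * lambda1 * delta, 0)
    if (max(abs(bn - b)) < tol) return(bn)
    b <- bn
  }
  b
}

# Full-enumeration two-sided Mann-Whitney p-value: every assignment of the
# pooled values into groups of sizes (n1, n2), rank-sum statistic with
# midranks.
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# Exhaustive hypergeometric upper tail: enumerate every possible draw of
# `list_size` genes from the background and count overlaps >= observed.
hyper_enum_oracle <- function(overlap, set_size, bg_size, list_size) {
  draws <- combn(bg_size, list_size)
  in_set <- draws <= set_size  # wlog the first set_size genes form the set
  mean(colSums(in_set) >= overlap)
}

# AUC by explicit pair counting.
auc_pairs_oracle <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Two-group log-rank statistic by direct tabulation over distinct event
# times (observed - expected, hypergeometric variance).
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  dtimes <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in dtimes) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# KKT residual of a weighted-lasso solution: max violation of the
# stationarity conditions, should be ~0 at convergence.
kkt_violation <- function(y, X, beta, delta, lambda1) {
  n <- nrow(X)
  grad <- drop(crossprod(X, y - X %*% beta)) / n
  viol_zero <- abs(grad) - lambda1 * delta
  viol_zero[beta != 0] <- -Inf
  viol_nz <- abs(grad - lambda1 * delta * sign(beta))
  viol_nz[beta == 0] <- 0
  max(c(viol_zero, viol_nz))
}

# Standardize columns with the population (divide-by-n) convention.
std_cols <- function(X) {
  mu <- colMeans(X)
  s <- sqrt(colMeans(X^2) - mu^2)
  sweep(sweep(X, 2, mu), 2, s, "/")
}

# Small planted-signal regression instance shared by several tests.
make_instance <- function(seed, n = 50, M = 5, beta_true = NULL,
                          noise_sd = 1) {
  set.seed(seed)
  X <- std_cols(matrix(rnorm(n * M), n, M))
  if (is.null(beta_true)) beta_true <- numeric(M)
  y <- drop(X %*% beta_true) + rnorm(n, sd = noise_sd)
  y <- y - mean(y)
  list(y = y, X = X)
}
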