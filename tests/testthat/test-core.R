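test_that("soft threshold is the absolute-value proximal map", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_error(soft_threshold(1, -1), "non-negative")
})

test_that("penalty scale follows the sigmoid of weighted impact scores", {
  F1 <- cbind(f = c(log(3), 0, -log(3)))
  expect_equal(unname(penalty_scale(0, F1)), rep(0.5, 3))
  expect_equal(unname(penalty_scale(1, F1, mode = "literal"))[1], 0.75)
  expect_equal(unname(penalty_scale(1, F1, mode = "oriented"))[1], 0.25)
  # oriented mode: strongly damaging alleles clipped at the floor
  F2 <- cbind(f = 10)
  expect_equal(unname(penalty_scale(1, F2, mode = "oriented")), 0.05)
  expect_lt(max(penalty_scale(5, F1, mode = "literal")), 1)
  expect_error(penalty_scale(c(1, 2), F1), "features")
})

test_that("weighted lasso recovers OLS at lambda 0 and zeroes at the null threshold", {
  set.seed(21)
  x <- std_cols(matrix(rnorm(40), 40, 1))
  y <- drop(2 * x)
  b <- fit_weighted_lasso(y, x, delta = 1, lambda1 = 0)
  expect_equal(as.numeric(b), 2, tolerance = 1e-8)

  inst <- make_instance(2, n = 60, M = 4, beta_true = c(1, 0, 0, 0))
  delta <- c(0.5, 1, 1, 2)
  lmax <- max(abs(crossprod(inst$X, inst$y)) / (60 * delta))
  b0 <- fit_weighted_lasso(inst$y, inst$X, delta, lmax * 1.0001)
  expect_true(all(b0 == 0))
  b1 <- fit_weighted_lasso(inst$y, inst$X, delta, lmax * 0.95)
  expect_gt(sum(b1 != 0), 0)
})

test_that("coordinate descent agrees with a proximal-gradient oracle", {
  for (s in 1:20) {
    inst <- make_instance(100 + s, n = 50, M = 5,
                          beta_true = c(2, -1, 0, 0, 0.5))
    delta <- runif(5, 0.3, 1.5)
    b_cd <- fit_weighted_lasso(inst$y, inst$X, delta, lambda1 = 0.1,
                               tol = 1e-10)
    b_pg <- prox_lasso_oracle(inst$y, inst$X, delta, lambda1 = 0.1)
    expect_lt(max(abs(b_cd - b_pg)), 1e-6)
  }
})

test_that("with unit penalty scales the fit matches a plain lasso", {
  skip_if_not_installed("glmnet")
  for (s in 1:20) {
    inst <- make_instance(200 + s, n = 50, M = 5,
                          beta_true = c(1.5, 0, -0.8, 0, 0))
    lam <- 0.15
    b_cd <- fit_weighted_lasso(inst$y, inst$X, rep(1, 5), lam, tol = 1e-10)
    g <- glmnet::glmnet(inst$X, inst$y, lambda = lam, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
    expect_lt(max(abs(b_cd - as.numeric(g$beta))), 1e-6)
  }
})

test_that("model objective evaluates all three terms", {
  # penalties vanish at beta = 0, w = 0: objective is sum ||y_j||^2 / (2n)
  set.seed(4)
  Y <- matrix(rnorm(20), 10, 2)
  X <- std_cols(matrix(rbinom(30, 1, 0.4) + 0.0, 10, 3))
  obj0 <- model_objective(Y, X, matrix(0, 3, 2), rep(1, 3), 0.5, 0.1)
  expect_equal(obj0, sum(Y^2) / 20)

  # exact-fit residual term is zero
  y <- c(1, -1); x <- matrix(c(1, -1), 2, 1)
  expect_equal(model_objective(matrix(y), x, matrix(1), 1, 0, 0), 0)

  # direct arithmetic on a tiny instance with every term nonzero
  Y2 <- matrix(c(1, 2, 3, 4), 2, 2)
  X2 <- matrix(c(1, -1, 0.5, 0.5), 2, 2)
  B2 <- matrix(c(0.5, 0, -1, 2), 2, 2)
  delta <- c(0.4, 0.8); l1 <- c(0.3, 0.2); l2 <- c(0.1, 0.05); w <- c(1, 2)
  hand <- {
    r <- Y2 - X2 %*% B2
    sum(colSums(r^2) / 4 + l1 * colSums(abs(B2) * delta)) + sum(l2) * sum(w^2)
  }
  expect_equal(model_objective(Y2, X2, B2, delta, l1, l2, w), hand)
})

test_that("cross-validation picks heavy shrinkage under the null", {
  # the minimum rule occasionally dips to a small lambda on a lucky fold
  # split, so both properties are asserted as a strong majority over seeds
  picks_top_quartile <- 0; sparse_seeds <- 0
  for (s in 1:10) {
    inst <- make_instance(300 + s, n = 100, M = 10)
    sel <- select_lambdas_cv(inst$y, inst$X, rep(1, 10), seed = s)
    q <- mean(sel$lambda1_grid <= sel$lambda1)  # fraction of grid at/below
    picks_top_quartile <- picks_top_quartile + (q >= 0.75)
    b <- fit_weighted_lasso(inst$y, inst$X, rep(1, 10), sel$lambda1)
    sparse_seeds <- sparse_seeds + (mean(b == 0) >= 0.9)
  }
  expect_gte(picks_top_quartile, 8)
  expect_gte(sparse_seeds, 8)
})

test_that("cross-validation keeps a strongly planted predictor", {
  for (s in 1:5) {
    inst <- make_instance(400 + s, n = 100, M = 8,
                          beta_true = c(3, rep(0, 7)), noise_sd = 0.1)
    sel <- select_lambdas_cv(inst$y, inst$X, rep(1, 8), seed = s)
    b <- fit_weighted_lasso(inst$y, inst$X, rep(1, 8), sel$lambda1)
    expect_true(b[1] != 0)
  }
})

test_that("cross-validation is deterministic given the seed", {
  inst <- make_instance(7, n = 50, M = 5)
  s1 <- select_lambdas_cv(inst$y, inst$X, rep(1, 5), seed = 99)
  s2 <- select_lambdas_cv(inst$y, inst$X, rep(1, 5), seed = 99)
  expect_identical(s1$folds, s2$folds)
  expect_identical(s1$lambda1, s2$lambda1)
  expect_identical(s1$cv_error, s2$cv_error)
})

test_that("weight update shrinks to zero without coefficients and stays non-negative", {
  set.seed(31)
  F <- matrix(rnorm(20), 10, 2)
  w <- update_weights(matrix(0, 10, 3), F, lambda1 = 0.1, lambda2 = 0.1,
                      w = c(0.5, 1.2))
  expect_lt(max(abs(w)), 1e-4)

  # any descent path stays in the non-negative orthant
  beta <- matrix(rnorm(30), 10, 3)
  w2 <- update_weights(beta, F, 0.1, 0.01, c(0.3, 0.3))
  expect_true(all(w2 >= 0))
})

test_that("weight update favors the informative feature", {
  wins <- 0
  for (s in 1:10) {
    set.seed(500 + s)
    M <- 40
    selected <- seq_len(8)  # alleles with large fitted |beta| mass
    beta <- matrix(0, M, 30)
    beta[selected, sample(30, 10)] <- 1
    f_info <- rnorm(M) + 2 * (seq_len(M) %in% selected)
    f_noise <- rnorm(M)
    F <- scale(cbind(info = f_info, noise = f_noise))
    w <- update_weights(beta, F, lambda1 = 0.1, lambda2 = 0.01, w = c(0, 0))
    wins <- wins + (w[1] > w[2])
  }
  expect_gte(wins, 6)
})

test_that("homogeneity: scaling y and lambda1 together scales the solution", {
  inst <- make_instance(17, n = 50, M = 5, beta_true = c(1, -2, 0, 0, 0))
  delta <- c(0.5, 1, 1, 0.7, 1)
  b <- fit_weighted_lasso(inst$y, inst$X, delta, 0.2, tol = 1e-10)
  b_scaled <- fit_weighted_lasso(3 * inst$y, inst$X, delta, 3 * 0.2,
                                 tol = 1e-10)
  expect_equal(as.numeric(b_scaled), as.numeric(3 * b), tolerance = 1e-7)
})

test_that("support size is monotone along a decreasing warm-started path", {
  for (s in 1:10) {
    inst <- make_instance(600 + s, n = 50, M = 5,
                          beta_true = c(2, 1, -1, 0, 0))
    delta <- rep(1, 5)
    lmax <- max(abs(crossprod(inst$X, inst$y)) / (50 * delta))
    path <- exp(seq(log(lmax), log(0.01 * lmax), length.out = 20))
    B <- exdriver:::.cd_path(inst$X, inst$y, delta, path, 1e-8, 10000L)
    nnz <- colSums(B != 0)
    expect_true(all(diff(nnz) >= 0))
  }
})

test_that("full model fit satisfies its contracts on planted data", {
  ds <- simulate_dataset(simulation_config(
    n_samples = 80, n_genes = 40, n_alleles = 12, n_drivers = 2,
    genes_per_driver = 8, seed = 42))
  ft <- build_feature_table(ds$features)
  fit <- exdriver(ds$expression, ds$mutations, ft, seed = 42)

  # objective never increases from a coefficient step to the weight step
  tr <- fit$objective_trace
  steps <- names(tr)
  for (i in which(steps == "weights"))
    expect_lte(tr[i], tr[i - 1] + 1e-9)

  # KKT certificate per gene at the final coefficients
  Yc <- sweep(fit$Y, 2, fit$y_center)
  worst <- max(vapply(seq_len(ncol(fit$beta)), function(j)
    kkt_violation(Yc[, j], fit$X, fit$beta[, j], fit$delta,
                  fit$lambda1[j]), numeric(1)))
  expect_lt(worst, 1e-6)

  # penalty scales live in [delta_min, 1); uniform start would be 0.5
  expect_true(all(fit$delta >= 0.05 & fit$delta < 1))
  expect_true(all(fit$r2 >= 0 & fit$r2 <= 1, na.rm = TRUE))
})

test_that("degenerate columns are dropped with a warning, not an error", {
  ds <- simulate_dataset(simulation_config(
    n_samples = 50, n_genes = 20, n_alleles = 8, n_drivers = 1,
    genes_per_driver = 5, seed = 9))
  Y <- ds$expression; Y[, 3] <- 5  # constant gene
  X <- ds$mutations; X[, 2] <- 0L  # never-mutated allele
  expect_warning(expect_warning(
    fit <- exdriver(Y, X, NULL, seed = 9),
    "constant gene"), "constant mutation")
  expect_equal(ncol(fit$beta), 19)
  expect_equal(nrow(fit$beta), 7)
})

test_that("variance explained matches direct arithmetic and its bounds", {
  ds <- simulate_dataset(simulation_config(
    n_samples = 60, n_genes = 25, n_alleles = 10, n_drivers = 2,
    genes_per_driver = 6, seed = 13))
  fit <- exdriver(ds$expression, ds$mutations, NULL, seed = 13)
  r2 <- variance_explained(fit)
  Yc <- sweep(fit$Y, 2, fit$y_center)
  rss <- colSums((Yc - fit$X %*% fit$beta)^2)
  expect_equal(unname(r2), unname(pmax(0, 1 - rss / colSums(Yc^2))))

  # noiseless planted data at vanishing penalty: residual -> 0, R2 -> 1
  inst <- make_instance(3, n = 50, M = 3, beta_true = c(1, 2, -1),
                        noise_sd = 0)
  b <- fit_weighted_lasso(inst$y, inst$X, rep(1, 3), 1e-10, tol = 1e-12)
  r2_exact <- 1 - sum((inst$y - inst$X %*% b)^2) / sum(inst$y^2)
  expect_equal(r2_exact, 1, tolerance = 1e-6)
})

test_that("prior-free mode reduces to a plain per-gene lasso", {
  ds <- simulate_dataset(simulation_config(
    n_samples = 60, n_genes = 10, n_alleles = 6, n_drivers = 1,
    genes_per_driver = 4, seed = 77))
  fit <- exdriver(ds$expression, ds$mutations, NULL, seed = 77)
  expect_true(all(fit$delta == 1))
  expect_length(fit$weights, 0)
  # refitting one gene at the stored lambda with a plain lasso reproduces it
  Yc <- sweep(fit$Y, 2, fit$y_center)
  b <- fit_weighted_lasso(Yc[, 1], fit$X, rep(1, 6), fit$lambda1[1],
                          tol = 1e-10)
  expect_equal(as.numeric(b), unname(fit$beta[, 1]), tolerance = 1e-5)
})

test_that("model methods are coherent", {
  ds <- simulate_dataset(simulation_config(
    n_samples = 50, n_genes = 15, n_alleles = 6, n_drivers = 1,
    genes_per_driver = 5, seed = 8))
  fit <- exdriver(ds$expression, ds$mutations, NULL, seed = 8)
  expect_identical(coef(fit), fit$beta)
  expect_equal(predict(fit) + residuals(fit), fit$Y)
  expect_equal(dim(simulate(fit, nsim = 2, seed = 1)[[1]]), dim(fit$Y))
  expect_output(print(fit), "driver mutation model")
  expect_output(print(summary(fit)), "Top alleles")
})
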