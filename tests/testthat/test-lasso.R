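test_that("penalties at or above lambda_max give the closed-form null model", {
  ds <- make_binary_ds(n = 300, p = 5, seed = 11, beta_main = c(1, -1))
  D <- build_design(ds, lapply(ds$feature_names, main_term))
  lmax <- lasso_lambda_max(D, ds$y)
  m <- fit_lasso_logistic(D, ds$y, lmax * 1.000001)
  expect_identical(m$complexity, 0L)
  expect_equal(m$intercept, qlogis(mean(ds$y)), tolerance = 1e-8)
})

test_that("the unpenalized fit matches the Newton-Raphson MLE", {
  set.seed(31)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(0.5 * X[, 1] - 0.8 * X[, 3]))
  m <- fit_lasso_logistic(X, y, 0, standardize = "none")
  oracle <- logistic_mle(X, y)
  got <- c(m$intercept, m$coefficients[colnames(X)])
  expect_lt(max(abs(got - oracle), na.rm = TRUE), 1e-4)
})

test_that("solutions satisfy exact KKT conditions across random designs", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 120; p <- 7
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rbinom(n, 1, plogis(X[, 1] - X[, 2]))
    lam <- runif(1, 0.005, 0.1)
    m <- fit_lasso_logistic(X, y, lam, standardize = "none")
    beta <- setNames(numeric(p), colnames(X))
    beta[names(m$coefficients)] <- m$coefficients
    expect_lt(lasso_kkt(X, y, m$intercept, beta, lam), 1e-6)
    # the optimum dominates the all-zero feasible point
    expect_lte(lasso_objective(X, y, m$intercept, beta, lam),
               lasso_objective(X, y, qlogis(mean(y)), numeric(p), lam))
  }
})

test_that("standardized fits back-transform to the original scale", {
  set.seed(13)
  n <- 400
  X <- cbind(d1 = rbinom(n, 1, 0.3), age = rnorm(n, 50, 12))
  y <- rbinom(n, 1, plogis(-1 + X[, "d1"] + 0.03 * (X[, "age"] - 50)))
  m <- fit_lasso_logistic(X, y, 0.002)
  # predictions computed from original-scale coefficients must match a
  # manual fit on the standardized design
  p1 <- predict_risk(m, X)
  Xs <- X
  Xs[, 2] <- (X[, 2] - mean(X[, 2])) / sd(X[, 2])
  m2 <- fit_lasso_logistic(Xs, y, 0.002, standardize = "none")
  p2 <- predict_risk(m2, Xs)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("warm-started path solutions equal cold-started solutions", {
  ds <- make_binary_ds(n = 400, p = 6, seed = 19, beta_main = c(1.5, -1))
  D <- build_design(ds, lapply(ds$feature_names, main_term))
  lmax <- lasso_lambda_max(D, ds$y)
  grid <- comologit:::lambda_grid(lmax, 20, 1e-3)
  path <- comologit:::lasso_path_fit(D, ds$y, grid, kkt_tol = 1e-9)
  for (l in c(5, 12, 20)) {
    cold <- fit_lasso_logistic(D, ds$y, grid[l], kkt_tol = 1e-9)
    warm <- comologit:::model_from_path(path, l, colnames(D))
    expect_equal(warm$intercept, cold$intercept, tolerance = 1e-6)
    expect_equal(warm$coefficients, cold$coefficients, tolerance = 1e-6)
  }
})

test_that("non-convergence raises an error carrying the last iterate", {
  ds <- make_binary_ds(n = 200, p = 4, seed = 23, beta_main = 2)
  D <- build_design(ds, lapply(ds$feature_names, main_term))
  err <- expect_error(
    fit_lasso_logistic(D, ds$y, 0.001, maxit = 1, kkt_tol = 1e-14),
    class = "comologit_convergence_error")
  expect_true(is.numeric(err$gradient_norm))
  expect_true(is.list(err$last_iterate))
})

test_that("predict_risk obeys the logistic link", {
  m <- comologit:::new_sparse_logit(0, c(a = 0), 1)  # intercept-only, 0
  D <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict_risk(m, D), rep(0.5, 10))
  m2 <- comologit:::new_sparse_logit(1.3, c(a = 0), 1)
  expect_true(all(predict_risk(m2, D) > 0.5))
  m3 <- comologit:::new_sparse_logit(0, c(zz = 2), 1)
  expect_error(predict_risk(m3, D), class = "comologit_validation_error")
})
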