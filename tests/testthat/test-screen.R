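test_that("strong hierarchy holds on every interaction set", {
  for (seed in 1:3) {
    ds <- make_binary_ds(n = 800, p = 6, seed = seed,
                         beta_main = c(1, -1), product_pair = c(3, 4),
                         beta_product = 1.5)
    iset <- discover_interactions(ds, ndi = 2, cv = FALSE)
    expect_true(all(as.vector(iset$pairs) %in% iset$main_effects))
    expect_lte(nrow(iset$pairs), 2)
  }
})

test_that("a strongly planted product pair is discovered first", {
  ds <- make_binary_ds(n = 3000, p = 8, seed = 5, beta_main = c(0.8, 0.5),
                       product_pair = c(2, 5), beta_product = 2)
  iset <- discover_interactions(ds, ndi = 1, cv = FALSE)
  expect_setequal(iset$pairs[1, ], c("d02", "d05"))
  # the exhaustive likelihood-ratio oracle agrees on the top pair
  top <- lr_pair_screen(ds)[1, ]
  expect_setequal(c(top$left, top$right), iset$pairs[1, ])
})

test_that("ndi = 0 returns no pairs and CV-selected main effects", {
  ds <- make_binary_ds(n = 800, p = 5, seed = 9, beta_main = c(1.5, -1.2))
  iset <- discover_interactions(ds, ndi = 0, cv = TRUE, seed = 1)
  expect_identical(nrow(iset$pairs), 0L)
  expect_true(all(c("d01", "d02") %in% iset$main_effects))
})

test_that("requesting more interactions than discoverable flags truncation", {
  ds <- make_binary_ds(n = 150, p = 3, seed = 13, intercept = -0.5)
  iset <- discover_interactions(ds, ndi = 40, cv = FALSE)
  expect_true(iset$truncated)
  expect_lt(nrow(iset$pairs), 40)
})

test_that("a single-class outcome is rejected", {
  X <- matrix(rbinom(60, 1, 0.5), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  ds <- como_data(X, rep(1, 20))
  expect_error(discover_interactions(ds, ndi = 1),
               class = "comologit_validation_error")
})

test_that("the solver objective matches the generic convex oracle", {
  set.seed(29)
  for (rep in 1:3) {
    n <- 60; p <- 3
    X <- matrix(rbinom(n * p, 1, 0.4), n, p,
                dimnames = list(NULL, paste0("d", 1:p)))
    y <- rbinom(n, 1, plogis(-0.5 + X[, 1] + 1.5 * X[, 1] * X[, 2]))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    pairs <- t(utils::combn(p, 2))
    lam <- 0.04
    fit <- comologit:::cpp_group_screen(X, y, pairs - 1L,
                                        integer(nrow(pairs)), c(lam), 1L, 1,
                                        sqrt(3), 1e-10, 20000, -1L, 1e-9)
    mine <- group_objective(X, y, pairs, fit$latent[, 1], lam)
    oracle <- group_lasso_admm(X, y, pairs, lam, iters = 1500)$objective
    expect_lt(abs(mine - oracle) / max(1, abs(oracle)), 1e-6)
  }
})

test_that("at lambda_max the group-lasso solution is intercept-only", {
  ds <- make_binary_ds(n = 400, p = 5, seed = 3, beta_main = c(1, 1))
  std <- comologit:::standardize_features(ds)
  pairs <- t(utils::combn(5, 2))
  fit <- comologit:::cpp_group_screen(std$Xw, ds$y, pairs - 1L,
                                      integer(nrow(pairs)), numeric(0), 5L,
                                      0.5, sqrt(3), 1e-9, 10000, -1L, 1e-7)
  expect_true(all(fit$mains[, 1] == 0))
  expect_true(all(fit$group_norms[, 1] == 0))
  expect_equal(fit$intercept[1], qlogis(mean(ds$y)), tolerance = 1e-6)
})

test_that("active interaction sets are (approximately) nested along the path", {
  nest_ok <- 0; total <- 0
  for (seed in 1:10) {
    ds <- make_binary_ds(n = 500, p = 5, seed = 100 + seed,
                         beta_main = c(1, -1), product_pair = c(1, 2),
                         beta_product = 1.5)
    std <- comologit:::standardize_features(ds)
    pairs <- t(utils::combn(5, 2))
    fit <- comologit:::cpp_group_screen(std$Xw, ds$y, pairs - 1L,
                                        integer(nrow(pairs)), numeric(0),
                                        15L, 0.01, sqrt(3), 1e-9, 10000,
                                        -1L, 1e-7)
    act <- apply(fit$group_norms > 0, 2, which, simplify = FALSE)
    for (l in seq_len(length(act) - 1)) {
      total <- total + 1
      if (all(act[[l]] %in% act[[l + 1]])) nest_ok <- nest_ok + 1
    }
  }
  expect_gte(nest_ok / total, 0.95)
})

test_that("screen models at stop and CV lambdas predict on the raw scale", {
  ds <- make_binary_ds(n = 1000, p = 5, seed = 7, beta_main = c(1, -1),
                       product_pair = c(1, 3), beta_product = 1.5)
  iset <- discover_interactions(ds, ndi = 1, cv = TRUE, seed = 11)
  for (which in c("stop", "cv")) {
    m <- screen_model(iset, which)
    D <- build_design(ds, m$terms)
    p_hat <- predict_risk(m, D)
    expect_true(all(p_hat > 0 & p_hat < 1))
    # original-scale coefficients must reproduce the working-scale fit
    l <- if (which == "stop") iset$stop_index else iset$cv_index
    std <- comologit:::standardize_features(ds)
    eta <- iset$fit$intercept[l] + drop(std$Xw %*% iset$fit$mains[, l])
    for (g in which(iset$fit$prod_coef[, l] != 0)) {
      jk <- iset$pairs_idx[g, ]
      eta <- eta + iset$fit$prod_coef[g, l] * std$Xw[, jk[1]] * std$Xw[, jk[2]]
    }
    expect_equal(p_hat, as.numeric(plogis(eta)), tolerance = 1e-8)
  }
})
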