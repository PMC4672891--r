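test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- emr_config(n_samples = 500, n_binary = 8, seed = 99)
  d1 <- simulate_emr(cfg)
  d2 <- simulate_emr(cfg)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$y, d2$y)
})

test_that("degenerate configurations are rejected", {
  expect_error(emr_config(n_samples = 1), class = "comologit_config_error")
  expect_error(emr_config(n_samples = 100, n_binary = 2,
                          prevalences = c(0.5, 1.5)),
               class = "comologit_config_error")
  expect_error(emr_config(n_samples = 100, n_binary = 2,
                          prevalences = c(0.5, 0.5),
                          effects = list(effect(main_term("dx09"), 1))),
               class = "comologit_config_error")
  expect_error(emr_config(n_samples = 100, n_binary = 2,
                          prevalences = c(0.5, 0.5),
                          effects = list(
                            effect(left_only_term("dx01", "los"), 1))),
               class = "comologit_config_error")
})

test_that("a null model with zero intercept yields a balanced outcome", {
  cfg <- emr_config(n_samples = 10000, n_binary = 5, effects = list(),
                    intercept = 0, seed = 3)
  ds <- simulate_emr(cfg)
  se <- sqrt(0.25 / ds$n)
  expect_lt(abs(mean(ds$y) - 0.5), 3 * se)
})

test_that("empirical prevalences track the configuration", {
  cfg <- emr_config(n_samples = 5000, n_binary = 20, effects = list(),
                    seed = 17)
  ds <- simulate_emr(cfg)
  p <- cfg$prevalences
  tol <- 4 * sqrt(p * (1 - p) / ds$n)
  expect_true(all(abs(colMeans(ds$X[, 1:20]) - p) <= tol))
})

test_that("the default intercept calibration hits the target event rate", {
  ds <- simulate_emr(emr_config(n_samples = 20000, seed = 5))
  expect_lt(abs(mean(attr(ds, "true_prob")) - 0.175), 1e-6)
  expect_lt(abs(mean(ds$y) - 0.175), 0.02)
})

test_that("switching effects raise risk only when exactly one dx is present", {
  cfg <- switching_config(n = 10000, seed = 21)
  ds <- simulate_emr(cfg)
  d1 <- ds$X[, "dx01"]; d2 <- ds$X[, "dx02"]
  one <- xor(d1 == 1, d2 == 1)
  expect_gt(mean(ds$y[one]), mean(ds$y[!one]))
  # both-present and neither-present groups share the same baseline risk
  expect_lt(abs(mean(ds$y[d1 == 1 & d2 == 1]) -
                mean(ds$y[d1 == 0 & d2 == 0])), 0.1)
})

test_that("an unpenalized refit on the true terms recovers planted effects", {
  cfg <- list(n2k = emr_config(n_samples = 2000, seed = 8),
              n20k = emr_config(n_samples = 20000, seed = 8))
  errs <- vapply(cfg, function(cc) {
    ds <- simulate_emr(cc)
    terms <- lapply(cc$effects, `[[`, "term")
    truth <- vapply(cc$effects, `[[`, numeric(1), "beta")
    D <- build_design(ds, terms)
    fit <- glm(ds$y ~ D, family = binomial())
    max(abs(coef(fit)[-1] - truth))
  }, numeric(1))
  expect_lt(errs["n20k"], errs["n2k"])   # consistency: error shrinks with n
  expect_lt(errs["n20k"], 0.3)
})

test_that("the latent-factor option induces indicator co-occurrence", {
  base <- emr_config(n_samples = 8000, n_binary = 6, effects = list(),
                     prevalences = rep(0.2, 6), seed = 4)
  cor0 <- cor(simulate_emr(base)$X[, 1:6])
  withcor <- emr_config(n_samples = 8000, n_binary = 6, effects = list(),
                        prevalences = rep(0.2, 6), factor_cor = 0.5,
                        seed = 4)
  cor1 <- cor(simulate_emr(withcor)$X[, 1:6])
  off <- upper.tri(cor0)
  expect_gt(mean(cor1[off]), mean(cor0[off]) + 0.1)
})
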