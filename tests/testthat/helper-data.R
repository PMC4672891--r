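# small in-code fixtures shared across tests

# plain binary-indicator dataset with an optional planted product effect
make_binary_ds <- function(n = 500, p = 6, prevalence = 0.3, seed = 1,
                           beta_main = NULL, product_pair = NULL,
                           beta_product = 0, intercept = -1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    X <- matrix(rbinom(n * p, 1, prevalence), n, p,
                dimnames = list(NULL, sprintf("d%02d", seq_len(p))))
    eta <- rep(intercept, n)
    if (!is.null(beta_main))
      eta <- eta + drop(X[, seq_along(beta_main), drop = FALSE] %*% beta_main)
    if (!is.null(product_pair))
      eta <- eta + beta_product * X[, product_pair[1]] * X[, product_pair[2]]
    y <- rbinom(n, 1, plogis(eta))
    # guarantee both classes for tiny n
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    como_data(X, y)
  })
}

tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# compact EMR scenario whose planted effects fit in few indicators
small_emr_config <- function(n = 1500, n_binary = 6, prevalence = 0.25,
                             seed = 1) {
  emr_config(
    n_samples = n, n_binary = n_binary,
    prevalences = rep(prevalence, n_binary),
    effects = list(
      effect(main_term("dx01"), 0.8),
      effect(main_term("dx02"), 0.6),
      effect(main_term("dx03"), -0.5),
      effect(product_term("dx04", "dx05"), 1.2),
      effect(main_term("los_log"), 0.4),
      effect(main_term("nchronic"), 0.3)),
    seed = seed)
}

# the switching scenario: complement effects planted, zero product effect
switching_config <- function(n = 10000, seed = 1) {
  emr_config(
    n_samples = n, n_binary = 12,
    prevalences = c(0.2, 0.2, rep(0.1, 10)),
    effects = list(
      effect(left_only_term("dx01", "dx02"), 2.0),
      effect(right_only_term("dx01", "dx02"), 2.0),
      effect(main_term("dx03"), 0.7),
      effect(main_term("dx04"), -0.6),
      effect(main_term("los_log"), 0.4),
      effect(main_term("nchronic"), 0.3)),
    seed = seed)
}
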