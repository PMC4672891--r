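#' Configure a synthetic EMR scenario
#'
#' Describes an electronic-medical-record-like table: many low-prevalence
#' binary diagnosis indicators, a few numeric covariates (length of stay,
#' its log, a chronic-condition count), and a binary outcome generated from
#' a logistic model over planted terms. The default configuration is the
#' "paper-like" scenario used throughout the package: 20,000 records, 50
#' indicators with a geometric prevalence ladder from 0.15 down to 0.005
#' (indicators are ordered by frequency, as most-frequent-diagnosis feature
#' sets are), lognormal length of stay plus its log companion, a
#' Poisson(1.5) chronic count, and an intercept calibrated so the positive
#' rate is about 0.175.
#'
#' Planted effects cover all term kinds: several main effects, one product
#' interaction, one "switching" pair (both complement terms at +2, zero
#' product effect -- risk is elevated when exactly one of the two diagnoses
#' is present), and a negative numeric-by-numeric interaction.
#'
#' @param n_samples number of records.
#' @param n_binary number of binary diagnosis indicators (named
#'   \code{dx01}, \code{dx02}, ...).
#' @param prevalences per-indicator Bernoulli probabilities in (0,1);
#'   default is the geometric ladder described above.
#' @param numeric_spec named list of numeric feature distributions; each
#'   entry is a list with a \code{dist} field: \code{"lognormal"}
#'   (\code{meanlog}, \code{sdlog}), \code{"poisson"} (\code{lambda}),
#'   \code{"normal"} (\code{mean}, \code{sd}) or \code{"log_of"}
#'   (\code{of} = another numeric feature, its log1p transform).
#' @param effects list of planted effects, each created with [effect()].
#'   When left at its default, effects referencing features that are not
#'   declared (e.g. \code{dx06} with \code{n_binary = 5}) are dropped, so
#'   the canonical scenario shrinks gracefully; explicitly supplied
#'   effects are validated strictly.
#' @param intercept logistic-scale intercept; \code{NULL} calibrates it on
#'   the realized covariates so that \code{mean(y)} matches
#'   \code{target_rate}.
#' @param target_rate desired positive rate when \code{intercept} is
#'   \code{NULL}.
#' @param factor_cor optional latent-factor tetrachoric correlation in
#'   [0,1) inducing diagnosis co-occurrence; 0 = independent indicators.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return An object of class \code{emr_config}.
#' @seealso [simulate_emr()], [effect()]
#' @export
emr_config <- function(n_samples = 20000,
                       n_binary = 50,
                       prevalences = NULL,
                       numeric_spec = default_numeric_spec(),
                       effects = default_effects(),
                       intercept = NULL,
                       target_rate = 0.175,
                       factor_cor = 0,
                       seed = 1L) {
  if (n_samples < 2) stop_config("n_samples must be at least 2")
  if (n_binary < 0) stop_config("n_binary must be nonnegative")
  if (is.null(prevalences)) prevalences <- prevalence_ladder(n_binary)
  if (length(prevalences) != n_binary)
    stop_config("prevalences must have one entry per binary indicator")
  if (any(prevalences <= 0) || any(prevalences >= 1))
    stop_config("all prevalences must lie strictly inside (0,1)")
  if (factor_cor < 0 || factor_cor >= 1)
    stop_config("factor_cor must lie in [0,1)")
  if (is.null(intercept) && (target_rate <= 0 || target_rate >= 1))
    stop_config("target_rate must lie strictly inside (0,1)")
  bin_names <- sprintf("dx%02d", seq_len(n_binary))
  num_names <- names(numeric_spec)
  feature_names <- c(bin_names, num_names)
  kinds <- c(rep("binary", n_binary), rep("numeric", length(num_names)))
  names(kinds) <- feature_names
  if (missing(effects)) {
    # the canonical scenario shrinks gracefully: default planted effects
    # whose features are not declared are dropped silently
    effects <- Filter(function(ef)
      all(term_features(ef$term) %in% feature_names), effects)
  }
  for (ef in effects) {
    if (!inherits(ef, "como_effect"))
      stop_config("effects must be built with effect()")
    for (f in term_features(ef$term)) {
      if (!f %in% feature_names)
        stop_config("planted effect references unknown feature '", f, "'")
    }
    if (ef$term$role %in% c("LEFT_ONLY", "RIGHT_ONLY")) {
      if (any(kinds[term_features(ef$term)] != "binary"))
        stop_config("complement effects may reference binary features only")
    }
  }
  structure(list(n_samples = n_samples, n_binary = n_binary,
                 prevalences = prevalences, numeric_spec = numeric_spec,
                 effects = effects, intercept = intercept,
                 target_rate = target_rate, factor_cor = factor_cor,
                 seed = seed, binary_names = bin_names,
                 numeric_names = num_names),
            class = "emr_config")
}

#' Planted effect for the synthetic generator
#'
#' @param term a [como_term] naming the generating model term.
#' @param beta its true logistic-scale coefficient.
#' @return An object of class \code{como_effect}.
#' @export
effect <- function(term, beta) {
  stopifnot(inherits(term, "como_term"), is.numeric(beta), length(beta) == 1L)
  structure(list(term = term, beta = beta), class = "como_effect")
}

# geometric prevalence ladder from 0.15 (most frequent dx) to 0.005
prevalence_ladder <- function(n_binary, hi = 0.15, lo = 0.005) {
  if (n_binary == 0) return(numeric(0))
  if (n_binary == 1) return(hi)
  hi * (lo / hi)^((seq_len(n_binary) - 1) / (n_binary - 1))
}

#' @rdname emr_config
#' @export
default_numeric_spec <- function() {
  list(
    los = list(dist = "lognormal", meanlog = 1.0, sdlog = 0.7),
    los_log = list(dist = "log_of", of = "los"),
    nchronic = list(dist = "poisson", lambda = 1.5)
  )
}

#' @rdname emr_config
#' @export
default_effects <- function() {
  list(
    effect(main_term("dx01"), 0.8),
    effect(main_term("dx02"), 0.6),
    effect(main_term("dx03"), -0.5),
    effect(main_term("los_log"), 0.5),
    effect(main_term("nchronic"), 0.3),
    effect(product_term("dx04", "dx05"), 1.0),
    effect(left_only_term("dx06", "dx07"), 2.0),
    effect(right_only_term("dx06", "dx07"), 2.0),
    effect(product_term("los_log", "nchronic"), -0.15)
  )
}

#' Generate a synthetic EMR dataset
#'
#' Draws binary indicators per their prevalences (optionally correlated
#' through a single latent factor), numeric covariates per their
#' distributions, and the outcome \code{y ~ Bernoulli(plogis(intercept +
#' sum(beta * term)))}. The same configuration and seed always yield a
#' bit-identical dataset. The realized per-record event probabilities and
#' the attained intercept are attached as attributes \code{"true_prob"}
#' and \code{"intercept"} for downstream checks.
#'
#' @param cfg an [emr_config].
#' @return A [como_data] object.
#' @export
simulate_emr <- function(cfg) {
  stopifnot(inherits(cfg, "emr_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    B <- matrix(0, n, cfg$n_binary,
                dimnames = list(NULL, cfg$binary_names))
    if (cfg$n_binary > 0) {
      if (cfg$factor_cor > 0) {
        z <- rnorm(n)
        r <- sqrt(cfg$factor_cor)
        for (j in seq_len(cfg$n_binary)) {
          lat <- r * z + sqrt(1 - cfg$factor_cor) * rnorm(n)
          B[, j] <- as.numeric(lat < stats::qnorm(cfg$prevalences[j]))
        }
      } else {
        for (j in seq_len(cfg$n_binary))
          B[, j] <- rbinom(n, 1L, cfg$prevalences[j])
      }
    }
    num_cols <- list()
    for (nm in cfg$numeric_names) {
      sp <- cfg$numeric_spec[[nm]]
      num_cols[[nm]] <- switch(sp$dist,
        lognormal = rlnorm(n, sp$meanlog, sp$sdlog),
        poisson = as.numeric(rpois(n, sp$lambda)),
        normal = rnorm(n, sp$mean %||% 0, sp$sd %||% 1),
        log_of = {
          base <- num_cols[[sp$of]]
          if (is.null(base))
            stop_config("log_of feature '", sp$of,
                        "' must be declared before '", nm, "'")
          log1p(base)
        },
        stop_config("unknown numeric distribution: ", sp$dist))
    }
    if (length(num_cols)) {
      X <- cbind(B, do.call(cbind, num_cols))
      colnames(X) <- c(cfg$binary_names, cfg$numeric_names)
    } else {
      X <- B
    }
    kinds <- c(rep("binary", cfg$n_binary),
               rep("numeric", length(cfg$numeric_names)))
    ds0 <- como_data(X, rep(c(0, 1), length.out = n), kinds = kinds)
    score <- rep(0, n)
    for (ef in cfg$effects)
      score <- score + ef$beta * build_design(ds0, list(ef$term))[, 1L]
    b0 <- cfg$intercept
    if (is.null(b0)) b0 <- calibrate_intercept(score, cfg$target_rate)
    prob <- plogis(b0 + score)
    y <- rbinom(n, 1L, prob)
    ds <- como_data(X, y, kinds = kinds)
    attr(ds, "true_prob") <- prob
    attr(ds, "intercept") <- b0
    attr(ds, "config") <- cfg
    ds
  })
}

# deterministic given the realized scores: mean plogis(b0 + s) = target
calibrate_intercept <- function(score, target) {
  f <- function(b0) mean(plogis(b0 + score)) - target
  uniroot(f, lower = -30, upper = 30, tol = 1e-10)$root
}
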