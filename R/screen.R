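# Step 1: hierarchical pairwise-interaction screening by overlapped
# group-lasso logistic regression.
#
# Every candidate pair (j,k) owns a latent group holding copies of both
# main effects and the product column, so the penalty can only activate an
# interaction together with its main effects (strong hierarchy). The path
# is walked from lambda_max downward and stops at the first lambda where
# the requested number of distinct interactions (NDI) is active.

#' Discover pairwise interactions under strong hierarchy
#'
#' Solves a logistic group-lasso whose groups are each main effect plus,
#' for every candidate feature pair, the latent group (main_j, main_k,
#' product_jk), along a decreasing log-spaced lambda path. The path stops
#' at the first lambda with at least \code{ndi} active interaction groups;
#' the first \code{ndi} interactions in order of path entry are returned
#' (ties broken by larger group-coefficient norm, then lexicographic pair
#' label). All binary-binary, binary-numeric and numeric-numeric pairs are
#' candidates. Numeric features are standardized inside the solver and
#' coefficients are reported back on the original scale.
#'
#' With \code{ndi = 0} no interactions are requested and the returned main
#' effects are those active at the cross-validation-selected lambda.
#'
#' @param ds a [como_data].
#' @param ndi number of interactions to discover (NDI), \code{>= 0}.
#' @param path_points,floor_ratio lambda grid: \code{path_points}
#'   log-spaced values from \code{lambda_max} down to
#'   \code{floor_ratio * lambda_max}.
#' @param cv also tune lambda by out-of-fold AUC over the (truncated)
#'   path; required for the cross-validated screen model and for
#'   \code{ndi = 0}.
#' @param folds CV folds.
#' @param seed seed controlling the CV fold assignment.
#' @param tol relative-objective convergence tolerance of the FISTA
#'   solver.
#' @param maxit iteration cap per lambda.
#' @return An \code{interaction_set} with fields \code{pairs} (two-column
#'   character matrix in discovery order), \code{main_effects},
#'   \code{ndi_requested}, \code{lambda_at_stop}, \code{truncated},
#'   and, when \code{cv = TRUE}, \code{lambda_cv} with the per-lambda AUC
#'   table. Strong hierarchy holds on every output: each pair's members
#'   are in \code{main_effects}.
#' @seealso [screen_model()], [expand_logical()]
#' @export
discover_interactions <- function(ds, ndi, path_points = 50,
                                  floor_ratio = 0.01, cv = TRUE, folds = 5,
                                  seed = NULL, tol = 1e-8, maxit = 10000) {
  stopifnot(inherits(ds, "como_data"), ndi >= 0)
  if (length(ds$feature_names) < 2)
    stop_validation("need at least two features to screen interactions")
  check_classes(ds$y)
  if (ndi == 0 && !cv)
    stop_config("ndi = 0 requires cv = TRUE to select the main-effect lambda")

  p <- length(ds$feature_names)
  std <- standardize_features(ds)
  pairs_idx <- t(utils::combn(p, 2))        # 1-based (j, k), j < k
  # every product column is scaled to unit sd inside the solver so pair
  # groups compete on correlation with the residual, not on prevalence
  scale_prod <- rep(TRUE, nrow(pairs_idx))

  fit <- cpp_group_screen(std$Xw, ds$y, pairs_idx - 1L,
                          as.integer(scale_prod), numeric(0),
                          as.integer(path_points), floor_ratio,
                          sqrt(3), tol, maxit,
                          if (ndi > 0) as.integer(ndi) else -1L, 1e-7)
  n_lam <- length(fit$lambdas)
  stop_index <- n_lam
  lambda_at_stop <- fit$lambdas[stop_index]

  # discovery order: path entry, then group norm at the stop lambda, then label
  found <- which(fit$entry >= 0)
  if (length(found)) {
    labs <- apply(pairs_idx[found, , drop = FALSE], 1, function(jk)
      paste(sort(ds$feature_names[jk]), collapse = " AND "))
    ord <- order(fit$entry[found], -fit$group_norms[found, stop_index], labs)
    found <- found[ord]
  }
  truncated <- ndi > 0 && length(found) < ndi
  if (ndi > 0) found <- head(found, ndi) else found <- integer(0)
  pairs <- matrix(ds$feature_names[t(pairs_idx[found, , drop = FALSE])],
                  ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("left", "right")))

  iset <- structure(list(
    pairs = pairs, ndi_requested = ndi,
    lambda_at_stop = lambda_at_stop, truncated = truncated,
    lambda_max = fit$lambda_max,
    feature_names = ds$feature_names, feature_kinds = ds$feature_kinds,
    pairs_idx = pairs_idx, scale_prod = scale_prod,
    center = std$center, scale = std$scale,
    fit = fit, stop_index = stop_index, folds = folds, seed = seed),
    class = "interaction_set")

  if (cv) {
    cvres <- screen_cv(ds, iset, folds = folds, seed = seed, tol = tol,
                       maxit = maxit)
    iset$lambda_cv <- cvres$lambda_cv
    iset$cv_index <- cvres$index
    iset$cv_table <- cvres$table
  }
  model_index <- if (ndi == 0) iset$cv_index else stop_index
  iset$main_effects <- active_main_effects(iset, model_index)
  iset
}

# all columns are centered so product candidates are interaction
# contrasts, not main-effect proxies; only numerics are scaled, keeping
# indicator coefficients on the per-diagnosis log-odds scale
standardize_features <- function(ds) {
  p <- length(ds$feature_names)
  center <- colMeans(ds$X)
  scale <- rep(1, p)
  for (j in seq_len(p)) {
    if (ds$feature_kinds[j] == "numeric") {
      s <- sd(ds$X[, j])
      if (s > 1e-12) scale[j] <- s
    }
  }
  Xw <- sweep(sweep(ds$X, 2, center, "-"), 2, scale, "/")
  list(Xw = Xw, center = center, scale = scale)
}

active_main_effects <- function(iset, l) {
  mains <- iset$feature_names[abs(iset$fit$mains[, l]) > 0]
  union(mains, as.vector(iset$pairs))
}

# out-of-fold AUC over the truncated grid, refitting the group lasso per fold
screen_cv <- function(ds, iset, folds, seed, tol, maxit) {
  grid <- iset$fit$lambdas
  fold_id <- with_seed(seed, stratified_folds(ds$y, folds))
  fold_auc <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(ds$y[tr])) < 2 || length(unique(ds$y[!tr])) < 2)
      stop_validation("fold ", f, " has a single outcome class; ",
                      "use fewer folds")
    tr_ds <- subset_data(ds, tr)
    std <- standardize_features(tr_ds)
    pf <- cpp_group_screen(std$Xw, tr_ds$y, iset$pairs_idx - 1L,
                           as.integer(iset$scale_prod), grid,
                           length(grid), 1, sqrt(3), tol, maxit, -1L, 1e-7)
    te_ds <- subset_data(ds, !tr)
    Xw_te <- sweep(sweep(te_ds$X, 2, std$center, "-"), 2, std$scale, "/")
    for (l in seq_along(grid)) {
      eta <- pf$intercept[l] + drop(Xw_te %*% pf$mains[, l])
      nz <- which(pf$prod_coef[, l] != 0)
      for (g in nz) {
        jk <- iset$pairs_idx[g, ]
        eta <- eta + pf$prod_coef[g, l] * Xw_te[, jk[1]] * Xw_te[, jk[2]]
      }
      fold_auc[f, l] <- auc(eta, te_ds$y)
    }
  }
  mean_auc <- colMeans(fold_auc)
  i_cv <- which(mean_auc >= max(mean_auc) - 1e-12)[1L]
  list(lambda_cv = grid[i_cv], index = i_cv,
       table = data.frame(lambda = grid, mean_auc = mean_auc,
                          se_auc = apply(fold_auc, 2, sd) / sqrt(folds)))
}

#' Sparse model from the interaction screen
#'
#' Extracts the group-lasso model (aggregated main effects plus product
#' interactions, on the original feature scale) either at the lambda where
#' the path stopped with the requested number of interactions
#' (\code{"stop"}) or at the cross-validation-selected lambda
#' (\code{"cv"}). This is the baseline ("interaction-only") arm of the
#' evaluation protocol: it carries no Boolean complement features.
#'
#' @param iset an \code{interaction_set}.
#' @param which \code{"cv"} or \code{"stop"}.
#' @return A \code{sparse_logit} whose terms are MAIN and PRODUCT
#'   descriptors.
#' @export
screen_model <- function(iset, which = c("cv", "stop")) {
  which <- match.arg(which)
  l <- if (which == "stop") iset$stop_index else {
    if (is.null(iset$cv_index))
      stop_config("interaction set was built with cv = FALSE; ",
                  "no cross-validated lambda is available")
    iset$cv_index
  }
  fit <- iset$fit
  cn <- iset$center
  sc <- iset$scale
  nms <- iset$feature_names
  beta <- fit$mains[, l] / sc
  b0 <- fit$intercept[l] - sum(fit$mains[, l] * cn / sc)
  prod_coefs <- numeric(0)
  prod_terms <- list()
  for (g in which(fit$prod_coef[, l] != 0)) {
    jk <- iset$pairs_idx[g, ]
    d <- fit$prod_coef[g, l] / (sc[jk[1]] * sc[jk[2]])
    beta[jk[1]] <- beta[jk[1]] - d * cn[jk[2]]
    beta[jk[2]] <- beta[jk[2]] - d * cn[jk[1]]
    b0 <- b0 + d * cn[jk[1]] * cn[jk[2]]
    tm <- product_term(nms[jk[1]], nms[jk[2]])
    prod_terms <- c(prod_terms, list(tm))
    prod_coefs <- c(prod_coefs, stats::setNames(d, term_label(tm)))
  }
  main_terms <- lapply(nms[beta != 0], main_term)
  coefs <- c(stats::setNames(beta[beta != 0], term_labels(main_terms)),
             prod_coefs)
  new_sparse_logit(b0, coefs,
                   if (which == "stop") iset$lambda_at_stop else iset$lambda_cv,
                   terms = c(main_terms, prod_terms))
}

#' @export
print.interaction_set <- function(x, ...) {
  cat("<interaction_set> NDI requested ", x$ndi_requested, ", found ",
      nrow(x$pairs), if (isTRUE(x$truncated)) " (truncated)" else "",
      "\n", sep = "")
  cat("  lambda_at_stop = ", format(x$lambda_at_stop, digits = 4), sep = "")
  if (!is.null(x$lambda_cv))
    cat(", lambda_cv = ", format(x$lambda_cv, digits = 4), sep = "")
  cat("\n  main effects: ", length(x$main_effects), "\n", sep = "")
  if (nrow(x$pairs))
    for (i in seq_len(nrow(x$pairs)))
      cat("  ", i, ". ", x$pairs[i, 1], " AND ", x$pairs[i, 2], "\n",
          sep = "")
  invisible(x)
}
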