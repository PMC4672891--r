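# Step 3: lasso logistic regression over the expanded design, with
# 5-fold cross-validated AUC tuning under the OPT and 1SE rules.

# identify 0/1 design columns; numerics get centered/scaled internally so
# the l1 penalty is comparable across columns, indicators stay raw so their
# coefficients keep their per-diagnosis interpretation
standardize_design <- function(design, standardize = c("auto", "none")) {
  standardize <- match.arg(standardize)
  p <- ncol(design)
  center <- rep(0, p)
  scale <- rep(1, p)
  if (standardize == "auto") {
    for (j in seq_len(p)) {
      if (!is_binary_values(design[, j])) {
        center[j] <- mean(design[, j])
        s <- sd(design[, j])
        if (s > 1e-12) scale[j] <- s
      }
    }
  }
  Xw <- sweep(sweep(design, 2, center, "-"), 2, scale, "/")
  list(Xw = Xw, center = center, scale = scale)
}

#' Smallest penalty that zeroes every lasso coefficient
#'
#' Computed from the gradient of the logistic log-likelihood at the
#' intercept-only (null) model: \code{max_j |x_j' (y - mean(y))| / n} on
#' the internally standardized design.
#'
#' @param design design matrix.
#' @param y binary outcome.
#' @param standardize \code{"auto"} standardizes non-0/1 columns.
#' @return The scalar \code{lambda_max}.
#' @export
lasso_lambda_max <- function(design, y, standardize = "auto") {
  std <- standardize_design(design, standardize)
  max(abs(crossprod(std$Xw, y - mean(y)))) / length(y)
}

lambda_grid <- function(lmax, nlambda, floor_ratio) {
  exp(seq(log(lmax), log(lmax * floor_ratio), length.out = nlambda))
}

new_sparse_logit <- function(intercept, coefs, lambda, terms = NULL,
                             kkt = NA_real_, iterations = NA_integer_) {
  coefs <- coefs[coefs != 0]
  structure(list(intercept = intercept, coefficients = coefs,
                 lambda_used = lambda, complexity = length(coefs),
                 terms = terms, kkt = kkt, iterations = iterations),
            class = "sparse_logit")
}

#' @export
print.sparse_logit <- function(x, ...) {
  cat("<sparse_logit> lambda = ", format(x$lambda_used, digits = 4),
      ", complexity = ", x$complexity,
      " nonzero coefficients, intercept = ",
      sprintf("%.4f", x$intercept), "\n", sep = "")
  if (x$complexity > 0) {
    show <- sort(abs(x$coefficients), decreasing = TRUE)
    show <- x$coefficients[names(head(show, 10))]
    for (nm in names(show))
      cat(sprintf("  %-45s %+.4f\n", nm, show[[nm]]))
    if (x$complexity > 10) cat("  ...\n")
  }
  invisible(x)
}

#' @export
coef.sparse_logit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

check_classes <- function(y) {
  if (!is_binary_values(y)) stop_validation("outcome must be 0/1")
  if (length(unique(y)) < 2)
    stop_validation("both outcome classes must be present")
}

#' Lasso-penalized logistic regression at a fixed penalty
#'
#' Minimizes \code{(1/n) * logistic negative log-likelihood +
#' lambda * sum(|beta|)} with an unpenalized intercept, by cyclic
#' coordinate descent on the quadratic-majorized working response. The
#' solution is verified against the exact Karush-Kuhn-Tucker conditions;
#' coefficients that are exactly zero are dropped. Coefficients are
#' reported on the original column scale.
#'
#' @param design numeric design matrix with column labels (typically from
#'   [build_design()]).
#' @param y binary 0/1 outcome.
#' @param lambda nonnegative penalty.
#' @param standardize \code{"auto"} (default) standardizes non-0/1 columns
#'   internally and back-transforms; \code{"none"} penalizes raw columns.
#' @param tol,maxit,kkt_tol solver controls: inner coordinate-descent
#'   change tolerance, outer iteration cap, and the KKT violation bound
#'   declared as convergence.
#' @return A \code{sparse_logit} model object.
#' @export
fit_lasso_logistic <- function(design, y, lambda, standardize = "auto",
                               tol = 1e-12, maxit = 500, kkt_tol = 1e-7) {
  stopifnot(is.matrix(design), nrow(design) == length(y), lambda >= 0)
  if (any(!is.finite(design))) stop_validation("design must be finite")
  check_classes(y)
  fit <- lasso_path_fit(design, y, lambda, standardize, tol, maxit, kkt_tol)
  if (!fit$converged[1]) {
    cond <- structure(
      class = c("comologit_convergence_error", "error", "condition"),
      list(message = paste0("lasso solver did not reach KKT tolerance ",
                            kkt_tol, "; max violation ",
                            format(fit$kkt[1], digits = 4)),
           call = sys.call(),
           last_iterate = list(intercept = fit$intercept[1],
                               coefficients = fit$beta[, 1]),
           gradient_norm = fit$kkt[1]))
    stop(cond)
  }
  model_from_path(fit, 1L, colnames(design))
}

# shared path driver; lambda may be a grid (decreasing) or a single value
lasso_path_fit <- function(design, y, lambda, standardize = "auto",
                           tol = 1e-12, maxit = 500, kkt_tol = 1e-7) {
  std <- standardize_design(design, standardize)
  out <- cpp_lasso_path(std$Xw, y, as.numeric(lambda), tol, maxit, kkt_tol)
  # back-transform to the original column scale
  beta_orig <- out$beta / std$scale
  int_orig <- out$intercept - colSums(out$beta * std$center / std$scale)
  list(lambda = as.numeric(lambda), beta = beta_orig, intercept = int_orig,
       beta_std = out$beta, intercept_std = out$intercept,
       kkt = out$kkt, iterations = out$iterations,
       converged = as.logical(out$converged), objective = out$objective,
       center = std$center, scale = std$scale)
}

model_from_path <- function(fit, l, labels) {
  coefs <- stats::setNames(fit$beta[, l], labels)
  new_sparse_logit(fit$intercept[l], coefs, fit$lambda[l],
                   kkt = fit$kkt[l], iterations = fit$iterations[l])
}

#' Predicted event probabilities from a sparse model
#'
#' @param model a \code{sparse_logit}.
#' @param design design matrix whose column labels cover the model's
#'   selected terms.
#' @return Per-row probabilities in (0,1).
#' @export
predict_risk <- function(model, design) {
  stopifnot(inherits(model, "sparse_logit"))
  need <- names(model$coefficients)
  missing_cols <- setdiff(need, colnames(design))
  if (length(missing_cols))
    stop_validation("design lacks model terms: ",
                    paste(missing_cols, collapse = ", "))
  eta <- rep(model$intercept, nrow(design))
  if (length(need))
    eta <- eta + drop(design[, need, drop = FALSE] %*% model$coefficients)
  as.numeric(plogis(eta))
}

#' Cross-validated penalty tuning by held-out AUC
#'
#' Fits the lasso path on the full data over a log-spaced grid from
#' \code{lambda_max} down to \code{floor_ratio * lambda_max}, then
#' estimates per-lambda out-of-fold AUC over stratified folds. Two rules
#' are reported: \code{lambda_opt} maximizes mean AUC (ties go to the
#' largest, i.e. sparsest, lambda) and \code{lambda_1se} is the largest
#' lambda whose mean AUC is within one standard error (fold standard
#' deviation divided by \code{sqrt(folds)}) of the maximum.
#'
#' @param design,y design matrix and binary outcome.
#' @param folds number of stratified CV folds.
#' @param nlambda,floor_ratio grid parameters.
#' @param standardize see [fit_lasso_logistic()].
#' @param seed integer seed making the fold assignment a pure function of
#'   \code{(seed, n, folds)}.
#' @param tol,maxit,kkt_tol solver controls.
#' @return A \code{como_cv} object with the grid, per-lambda mean and SE
#'   of AUC, both selected lambdas, and full-data models refit at each
#'   (\code{$model_opt}, \code{$model_1se}).
#' @export
cv_tune <- function(design, y, folds = 5, nlambda = 100, floor_ratio = 1e-4,
                    standardize = "auto", seed = NULL,
                    tol = 1e-12, maxit = 500, kkt_tol = 1e-7) {
  check_classes(y)
  n <- length(y)
  if (n < folds) stop_validation("need at least one observation per fold")
  lmax <- lasso_lambda_max(design, y, standardize)
  grid <- lambda_grid(lmax, nlambda, floor_ratio)
  full <- lasso_path_fit(design, y, grid, standardize, tol, maxit, kkt_tol)

  fold_id <- with_seed(seed, stratified_folds(y, folds))
  fold_auc <- matrix(NA_real_, folds, nlambda)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
      stop_validation("fold ", f, " has a single outcome class; ",
                      "use fewer folds")
    pf <- lasso_path_fit(design[tr, , drop = FALSE], y[tr], grid,
                         standardize, tol, maxit, kkt_tol)
    eta <- design[!tr, , drop = FALSE] %*% pf$beta
    eta <- sweep(eta, 2, pf$intercept, "+")
    fold_auc[f, ] <- apply(eta, 2, auc, labels = y[!tr])
  }
  mean_auc <- colMeans(fold_auc)
  se_auc <- apply(fold_auc, 2, sd) / sqrt(folds)
  i_opt <- which(mean_auc >= max(mean_auc) - 1e-12)[1L]  # largest lambda wins ties
  thr <- mean_auc[i_opt] - se_auc[i_opt]
  i_1se <- which(mean_auc >= thr - 1e-12)[1L]
  structure(list(lambdas = grid, mean_auc = mean_auc, se_auc = se_auc,
                 fold_auc = fold_auc, fold_id = fold_id,
                 lambda_opt = grid[i_opt], lambda_1se = grid[i_1se],
                 index_opt = i_opt, index_1se = i_1se,
                 model_opt = model_from_path(full, i_opt, colnames(design)),
                 model_1se = model_from_path(full, i_1se, colnames(design)),
                 path = full, labels = colnames(design), folds = folds,
                 seed = seed),
            class = "como_cv")
}

#' @export
print.como_cv <- function(x, ...) {
  cat("<como_cv> ", x$folds, "-fold AUC-tuned lasso path (",
      length(x$lambdas), " lambdas)\n", sep = "")
  cat(sprintf("  lambda_opt = %.5g (AUC %.4f, complexity %d)\n",
              x$lambda_opt, x$mean_auc[x$index_opt], x$model_opt$complexity))
  cat(sprintf("  lambda_1se = %.5g (AUC %.4f, complexity %d)\n",
              x$lambda_1se, x$mean_auc[x$index_1se], x$model_1se$complexity))
  invisible(x)
}
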