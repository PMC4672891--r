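#' Fit a comprehensible comorbidity risk model
#'
#' Runs the full three-stage pipeline on a patient-level table:
#' \enumerate{
#'   \item screen pairwise interactions under strong hierarchy with an
#'     overlapped group-lasso logistic path, stopping once \code{ndi}
#'     interactions are active ([discover_interactions()]);
#'   \item expand the selected terms with Boolean complement
#'     ("comorbidity") features for binary pairs ([expand_logical()]);
#'   \item prune the expanded design with lasso logistic regression tuned
#'     by cross-validated AUC ([cv_tune()]), keeping both the AUC-optimal
#'     (OPT) and the sparser one-standard-error (1SE) models.
#' }
#' The group-lasso model at its own cross-validated lambda is retained as
#' the interaction-only baseline.
#'
#' @param data a [como_data], or a data frame containing the outcome
#'   column.
#' @param outcome outcome column name when \code{data} is a data frame.
#' @param binary_columns optional explicit list of binary feature names
#'   (data-frame input only); otherwise 0/1 columns are auto-flagged.
#' @param ndi number of pairwise interactions to discover.
#' @param folds cross-validation folds for both tuning stages.
#' @param path_points,screen_floor screening-path grid controls.
#' @param lambda_points,lambda_floor final-lasso grid controls.
#' @param seed integer seed (controls fold assignment).
#' @return An object of class \code{comologit} with components
#'   \code{interactions} (the screened \code{interaction_set}),
#'   \code{terms} (expanded descriptors), \code{cv} (the \code{como_cv}
#'   tuning object) and \code{models} (\code{baseline}, \code{opt},
#'   \code{1se} as \code{sparse_logit}s). Supports \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{plot},
#'   \code{residuals} and \code{simulate}.
#' @examples
#' cfg <- emr_config(n_samples = 1500, n_binary = 8, seed = 42,
#'                   effects = list(effect(main_term("dx01"), 1),
#'                                  effect(product_term("dx02", "dx03"), 2)))
#' fit <- comologit(simulate_emr(cfg), ndi = 1, seed = 7)
#' print(fit)
#' coef(fit, rule = "1se")
#' @export
comologit <- function(data, outcome = "y", binary_columns = NULL, ndi = 10,
                      folds = 5, path_points = 50, screen_floor = 0.01,
                      lambda_points = 100, lambda_floor = 1e-4,
                      seed = NULL) {
  if (is.data.frame(data)) {
    if (!outcome %in% names(data))
      stop_config("outcome column '", outcome, "' not present")
    kinds <- NULL
    feats <- as.matrix(data[names(data) != outcome])
    if (!is.null(binary_columns))
      kinds <- ifelse(colnames(feats) %in% binary_columns,
                      "binary", "numeric")
    data <- como_data(feats, data[[outcome]], kinds = kinds,
                      outcome_name = outcome)
  }
  stopifnot(inherits(data, "como_data"))
  cl <- match.call()
  res <- with_seed(seed, {
    sub_seeds <- draw_seeds(2)
    iset <- discover_interactions(data, ndi, path_points = path_points,
                                  floor_ratio = screen_floor, cv = TRUE,
                                  folds = folds, seed = sub_seeds[1])
    terms <- expand_logical(iset, data)
    D <- build_design(data, terms)
    cv <- cv_tune(D, data$y, folds = folds, nlambda = lambda_points,
                  floor_ratio = lambda_floor, seed = sub_seeds[2])
    baseline <- screen_model(iset, "cv")
    list(iset = iset, terms = terms, cv = cv, baseline = baseline, D = D)
  })
  models <- list(baseline = res$baseline, opt = res$cv$model_opt,
                 `1se` = res$cv$model_1se)
  base_design <- build_design(data, res$baseline$terms)
  fitted <- list(baseline = predict_risk(res$baseline, base_design),
                 opt = predict_risk(res$cv$model_opt, res$D),
                 `1se` = predict_risk(res$cv$model_1se, res$D))
  structure(list(call = cl, interactions = res$iset, terms = res$terms,
                 cv = res$cv, models = models, fitted = fitted,
                 y = data$y, n = data$n,
                 feature_kinds = data$feature_kinds, ndi = ndi,
                 seed = seed),
            class = "comologit")
}

rule_model <- function(object, rule = c("1se", "opt", "baseline")) {
  rule <- match.arg(rule)
  object$models[[if (rule == "baseline") "baseline"
                 else if (rule == "opt") "opt" else "1se"]]
}

#' @export
print.comologit <- function(x, ...) {
  cat("Comprehensible comorbidity risk model\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  cat("Interactions discovered (NDI = ", x$ndi, "): ",
      nrow(x$interactions$pairs), "\n", sep = "")
  cat("Expanded terms: ", length(x$terms), "\n", sep = "")
  for (m in names(x$models))
    cat(sprintf("  %-9s complexity %3d  (lambda %.5g)\n", m,
                x$models[[m]]$complexity, x$models[[m]]$lambda_used))
  invisible(x)
}

#' @export
summary.comologit <- function(object, ...) {
  cv <- object$cv
  structure(list(call = object$call, ndi = object$ndi, n = object$n,
                 pairs = object$interactions$pairs,
                 auc_opt = cv$mean_auc[cv$index_opt],
                 auc_1se = cv$mean_auc[cv$index_1se],
                 models = object$models),
            class = "summary.comologit")
}

#' @export
print.summary.comologit <- function(x, ...) {
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat("n = ", x$n, ", NDI = ", x$ndi, "\n\n", sep = "")
  if (nrow(x$pairs)) {
    cat("Discovered interactions:\n")
    for (i in seq_len(nrow(x$pairs)))
      cat("  ", x$pairs[i, 1], " AND ", x$pairs[i, 2], "\n", sep = "")
  }
  cat(sprintf("\nCV AUC: OPT %.4f, 1SE %.4f\n", x$auc_opt, x$auc_1se))
  for (m in names(x$models)) {
    cat("\n--- ", m, " model ---\n", sep = "")
    print(x$models[[m]])
  }
  invisible(x)
}

#' @export
coef.comologit <- function(object, rule = "1se", ...) {
  coef(rule_model(object, rule))
}

#' @export
predict.comologit <- function(object, newdata = NULL, rule = "1se",
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  model <- rule_model(object, rule)
  if (is.null(newdata)) {
    p <- object$fitted[[if (rule == "baseline") "baseline"
                        else if (rule == "opt") "opt" else "1se"]]
  } else {
    if (is.data.frame(newdata)) {
      newdata <- como_data(as.matrix(newdata[!names(newdata) %in%
                                               "y"]),
                           rep(c(0, 1), length.out = nrow(newdata)))
    }
    design <- build_design(newdata, model$terms %||%
                             labels_to_terms(names(model$coefficients),
                                             object$terms))
    p <- predict_risk(model, design)
  }
  if (type == "response") p else qlogis(p)
}

# recover descriptor objects for a set of labels from the expanded term list
labels_to_terms <- function(labels, terms) {
  all_labels <- term_labels(terms)
  idx <- match(labels, all_labels)
  if (anyNA(idx))
    stop_validation("unknown term labels: ",
                    paste(labels[is.na(idx)], collapse = ", "))
  terms[idx]
}

#' @export
residuals.comologit <- function(object,
                                type = c("deviance", "pearson", "response"),
                                rule = "1se", ...) {
  type <- match.arg(type)
  p <- object$fitted[[if (rule == "baseline") "baseline"
                      else if (rule == "opt") "opt" else "1se"]]
  y <- object$y
  switch(type,
    response = y - p,
    pearson = (y - p) / sqrt(p * (1 - p)),
    deviance = sign(y - p) *
      sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p))))
}

#' @export
simulate.comologit <- function(object, nsim = 1, seed = NULL,
                               rule = "1se", ...) {
  p <- object$fitted[[if (rule == "baseline") "baseline"
                      else if (rule == "opt") "opt" else "1se"]]
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim, rbinom(length(p), 1L, p)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' @export
plot.comologit <- function(x, ...) {
  cv <- x$cv
  ll <- log10(cv$lambdas)
  plot(ll, cv$mean_auc, type = "l", xlab = "log10(lambda)",
       ylab = "cross-validated AUC", main = "AUC-tuned lasso path", ...)
  lines(ll, cv$mean_auc + cv$se_auc, lty = 3)
  lines(ll, cv$mean_auc - cv$se_auc, lty = 3)
  abline(v = log10(cv$lambda_opt), col = 2, lty = 2)
  abline(v = log10(cv$lambda_1se), col = 4, lty = 2)
  legend("bottomleft", c("OPT", "1SE"), col = c(2, 4), lty = 2, bty = "n")
  invisible(x)
}
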