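# Repeated hold-out evaluation, selection-frequency stability tables.

#' Area under the ROC curve
#'
#' The tie-corrected Mann-Whitney statistic: the probability that a random
#' positive case outscores a random negative one, counting ties as one
#' half, computed via mid-ranks.
#'
#' @param scores numeric scores (any monotone transform of risk).
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!is_binary_values(labels)) stop_validation("labels must be 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_validation("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated hold-out evaluation of the modelling pipeline
#'
#' For each repeat the data are split (stratified by outcome) into a
#' training fraction and a held-out test set; the full pipeline runs on
#' the training part, and three models are scored on the test part:
#' \describe{
#'   \item{baseline}{the hierarchical group-lasso interaction model at its
#'     cross-validation-selected lambda, without complement features;}
#'   \item{opt}{the complement-expanded lasso at the AUC-optimal lambda;}
#'   \item{1se}{the same at the one-standard-error lambda.}
#' }
#' Per repeat the test AUC and the model complexity (number of nonzero
#' coefficients) are recorded, along with the sign of every selected
#' coefficient for the stability tables. Summaries are the mean and the
#' 2.5/97.5 percentiles across repeats. Failed repeats are skipped with a
#' warning; more than 10\% failures aborts.
#'
#' @param ds a [como_data].
#' @param ndi number of interactions to screen (NDI).
#' @param repeats number of hold-out repetitions.
#' @param split_fraction training fraction (the classic protocol holds out
#'   one third).
#' @param folds CV folds used inside both tuning stages.
#' @param seed integer seed; a fixed \code{(seed, repeats)} yields an
#'   identical report.
#' @param path_points,floor_ratio screening-path grid controls.
#' @param nlambda,lambda_floor step-3 lasso grid controls.
#' @return A \code{como_eval} object.
#' @export
repeated_holdout <- function(ds, ndi, repeats = 100, split_fraction = 2 / 3,
                             folds = 5, seed = NULL,
                             path_points = 50, floor_ratio = 0.01,
                             nlambda = 100, lambda_floor = 1e-4) {
  stopifnot(inherits(ds, "como_data"), repeats >= 1,
            split_fraction > 0, split_fraction < 1)
  methods <- c("baseline", "opt", "1se")
  auc_s <- matrix(NA_real_, repeats, 3, dimnames = list(NULL, methods))
  cpx_s <- matrix(NA_integer_, repeats, 3, dimnames = list(NULL, methods))
  sel_opt <- vector("list", repeats)
  sel_1se <- vector("list", repeats)
  failed <- character(0)
  with_seed(seed, {
    repeat_seeds <- draw_seeds(repeats)
    for (r in seq_len(repeats)) {
      res <- tryCatch(
        with_seed(repeat_seeds[r], {
          sub_seeds <- draw_seeds(2)
          train <- stratified_split(ds$y, split_fraction)
          tr <- subset_data(ds, train)
          te <- subset_data(ds, !train)
          iset <- discover_interactions(tr, ndi, path_points = path_points,
                                        floor_ratio = floor_ratio,
                                        cv = TRUE, folds = folds,
                                        seed = sub_seeds[1])
          base <- screen_model(iset, "cv")
          terms <- expand_logical(iset, tr)
          D <- build_design(tr, terms)
          cvres <- cv_tune(D, tr$y, folds = folds, nlambda = nlambda,
                           floor_ratio = lambda_floor, seed = sub_seeds[2])
          Dte <- build_design(te, terms)
          Bte <- build_design(te, base$terms)
          list(
            auc = c(auc(predict_risk(base, Bte), te$y),
                    auc(predict_risk(cvres$model_opt, Dte), te$y),
                    auc(predict_risk(cvres$model_1se, Dte), te$y)),
            cpx = c(base$complexity, cvres$model_opt$complexity,
                    cvres$model_1se$complexity),
            sel_opt = cvres$model_opt$coefficients,
            sel_1se = cvres$model_1se$coefficients)
        }),
        error = function(e) e)
      if (inherits(res, "error")) {
        failed <- c(failed, conditionMessage(res))
        warning("repeat ", r, " failed and was skipped: ",
                conditionMessage(res))
        next
      }
      auc_s[r, ] <- res$auc
      cpx_s[r, ] <- res$cpx
      sel_opt[[r]] <- res$sel_opt
      sel_1se[[r]] <- res$sel_1se
    }
  })
  if (length(failed) > 0.1 * repeats)
    stop_validation("more than 10% of repeats failed; first error: ",
                    failed[1])
  ok <- !is.na(auc_s[, 1])
  summarise <- function(m) {
    t(apply(m[ok, , drop = FALSE], 2, function(v)
      c(mean = mean(v), p2.5 = unname(quantile(v, 0.025)),
        p97.5 = unname(quantile(v, 0.975)))))
  }
  structure(list(methods = methods, ndi = ndi, repeats = repeats,
                 auc_samples = auc_s[ok, , drop = FALSE],
                 complexity_samples = cpx_s[ok, , drop = FALSE],
                 auc_summary = summarise(auc_s),
                 complexity_summary = summarise(cpx_s),
                 selected_opt = sel_opt[ok], selected_1se = sel_1se[ok],
                 n_failed = length(failed), seed = seed,
                 split_fraction = split_fraction, folds = folds),
            class = "como_eval")
}

#' @export
print.como_eval <- function(x, ...) {
  cat("<como_eval> NDI = ", x$ndi, ", ", nrow(x$auc_samples),
      " of ", x$repeats, " repeats (", round(100 * x$split_fraction),
      "/", round(100 * (1 - x$split_fraction)), " split)\n", sep = "")
  cat("AUC (mean [2.5%, 97.5%]):\n")
  for (m in x$methods)
    cat(sprintf("  %-9s %.4f [%.4f, %.4f]\n", m,
                x$auc_summary[m, 1], x$auc_summary[m, 2],
                x$auc_summary[m, 3]))
  cat("Complexity (mean [2.5%, 97.5%]):\n")
  for (m in x$methods)
    cat(sprintf("  %-9s %.2f [%.1f, %.1f]\n", m,
                x$complexity_summary[m, 1], x$complexity_summary[m, 2],
                x$complexity_summary[m, 3]))
  invisible(x)
}

#' @export
plot.como_eval <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  boxplot(x$auc_samples, main = "Held-out AUC", ylab = "AUC", ...)
  boxplot(x$complexity_samples, main = "Model complexity",
          ylab = "nonzero coefficients", ...)
  invisible(x)
}

#' Selection-frequency stability table
#'
#' Ranks, for one coefficient sign, every model term ever selected across
#' the hold-out repeats by how often it appears with that sign under the
#' OPT rule, with the 1SE percentage alongside -- the layout of the
#' classic "most frequent positive/negative coefficients" comorbidity
#' tables. Rows are sorted by OPT percentage (descending), ties broken by
#' 1SE percentage, then label.
#'
#' @param x a \code{como_eval}, or a list of per-repeat OPT coefficient
#'   vectors (named numeric).
#' @param sign \code{"positive"} or \code{"negative"}.
#' @param models_1se per-repeat 1SE coefficient vectors when \code{x} is a
#'   plain list.
#' @return A data frame of class \code{como_freq} with columns
#'   \code{rank}, \code{variable}, \code{opt}, \code{one_se} (percentages
#'   in [0, 100]).
#' @export
frequency_table <- function(x, sign = c("positive", "negative"),
                            models_1se = NULL) {
  sign <- match.arg(sign)
  if (inherits(x, "como_eval")) {
    opt <- x$selected_opt
    se1 <- x$selected_1se
  } else {
    opt <- x
    se1 <- models_1se %||% vector("list", length(opt))
  }
  if (!length(opt)) stop_validation("at least one repeat is required")
  keep <- if (sign == "positive") function(v) names(v)[v > 0]
          else function(v) names(v)[v < 0]
  tab_opt <- table(unlist(lapply(opt, keep)))
  tab_1se <- table(unlist(lapply(se1, keep)))
  labels <- union(names(tab_opt), names(tab_1se))
  if (!length(labels)) {
    out <- data.frame(rank = integer(0), variable = character(0),
                      opt = numeric(0), one_se = numeric(0))
    class(out) <- c("como_freq", "data.frame")
    return(out)
  }
  pct <- function(tab) 100 * as.numeric(tab[labels]) / length(opt)
  p_opt <- ifelse(is.na(pct(tab_opt)), 0, pct(tab_opt))
  p_1se <- ifelse(is.na(pct(tab_1se)), 0, pct(tab_1se))
  ord <- order(-p_opt, -p_1se, labels)
  out <- data.frame(rank = seq_along(ord), variable = labels[ord],
                    opt = p_opt[ord], one_se = p_1se[ord],
                    row.names = NULL)
  attr(out, "sign") <- sign
  class(out) <- c("como_freq", "data.frame")
  out
}

#' @export
print.como_freq <- function(x, n = 10, ...) {
  cat("Most frequent ", attr(x, "sign") %||% "", " coefficients",
      " (% of repeats selected)\n", sep = "")
  df <- head(as.data.frame(x), n)
  if (!nrow(df)) {
    cat("  (none)\n")
    return(invisible(x))
  }
  cat(sprintf("  %4s  %-45s %6s %6s\n", "rank", "variable", "OPT", "1SE"))
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %4d  %-45s %6.1f %6.1f\n", df$rank[i], df$variable[i],
                df$opt[i], df$one_se[i]))
  invisible(x)
}
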