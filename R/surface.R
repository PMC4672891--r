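# Response-surface demonstration of an interaction between two numeric
# features (the Simpson's-paradox style picture: risk can fall when both
# covariates grow together even though each main effect is positive).

#' Predicted-risk surfaces with and without an interaction term
#'
#' Fits two unpenalized logistic models on the two named numeric
#' features -- \code{y ~ a + b} and \code{y ~ a + b + a:b} -- and
#' evaluates predicted risk on a rectangular grid spanning the observed
#' feature ranges.
#'
#' @param ds a [como_data].
#' @param feature_a,feature_b names of two numeric (or count-valued)
#'   features.
#' @param grid_points grid resolution per axis.
#' @return A \code{como_surface} with the axis grids and two risk
#'   matrices (\code{risk_without}, \code{risk_with}), all values in
#'   (0, 1).
#' @export
interaction_response_surface <- function(ds, feature_a, feature_b,
                                         grid_points = 25) {
  stopifnot(inherits(ds, "como_data"))
  for (f in c(feature_a, feature_b)) {
    if (!f %in% ds$feature_names)
      stop_validation("unknown feature '", f, "'")
    if (ds$feature_kinds[match(f, ds$feature_names)] != "numeric")
      stop_validation("feature '", f, "' must be numeric")
  }
  check_classes(ds$y)
  df <- data.frame(y = ds$y, a = ds$X[, feature_a], b = ds$X[, feature_b])
  fit_wo <- glm(y ~ a + b, data = df, family = binomial())
  fit_wi <- glm(y ~ a * b, data = df, family = binomial())
  for (fit in list(fit_wo, fit_wi)) {
    if (!fit$converged || any(abs(coef(fit)) > 30))
      stop_validation("logistic fit appears separable; consider a ",
                      "ridge-regularized fit instead")
  }
  ga <- seq(min(df$a), max(df$a), length.out = grid_points)
  gb <- seq(min(df$b), max(df$b), length.out = grid_points)
  grid <- expand.grid(a = ga, b = gb)
  shape <- function(fit) matrix(predict(fit, grid, type = "response"),
                                grid_points, grid_points)
  structure(list(feature_a = feature_a, feature_b = feature_b,
                 a_grid = ga, b_grid = gb,
                 risk_without = shape(fit_wo), risk_with = shape(fit_wi),
                 coef_without = coef(fit_wo), coef_with = coef(fit_wi)),
            class = "como_surface")
}

#' @export
print.como_surface <- function(x, ...) {
  cat("<como_surface> ", x$feature_a, " x ", x$feature_b, ", ",
      length(x$a_grid), "x", length(x$b_grid), " grid\n", sep = "")
  cat("  interaction coefficient: ",
      sprintf("%+.4f", x$coef_with[["a:b"]]), "\n", sep = "")
  invisible(x)
}

#' @export
plot.como_surface <- function(x, theta = 40, phi = 25, ...) {
  op <- par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
  on.exit(par(op))
  persp(x$a_grid, x$b_grid, x$risk_without, theta = theta, phi = phi,
        xlab = x$feature_a, ylab = x$feature_b, zlab = "risk",
        main = "without interaction", ticktype = "detailed", ...)
  persp(x$a_grid, x$b_grid, x$risk_with, theta = theta, phi = phi,
        xlab = x$feature_a, ylab = x$feature_b, zlab = "risk",
        main = "with interaction", ticktype = "detailed", ...)
  invisible(x)
}
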