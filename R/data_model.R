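#' EMR-style modelling datasets
#'
#' \code{como_data()} wraps a feature matrix and binary outcome into the
#' container used throughout the package. Columns are flagged as binary
#' (0/1 diagnosis indicators) or numeric; the flag controls which features
#' may take part in Boolean complement terms and which are standardized
#' inside the penalized solvers.
#'
#' @param X numeric matrix (or data frame) of features, with column names.
#' @param y binary outcome vector (0/1), \code{length(y) == nrow(X)}.
#' @param kinds character vector, one of \code{"binary"}/\code{"numeric"}
#'   per column. If \code{NULL}, a column whose observed values are all in
#'   \{0,1\} is auto-flagged binary.
#' @param outcome_name name used for the outcome column when writing CSV.
#' @return An object of class \code{como_data} with fields \code{X},
#'   \code{y}, \code{feature_names}, \code{feature_kinds}, \code{n}.
#' @export
como_data <- function(X, y, kinds = NULL, outcome_name = "y") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop_validation("X must be a numeric matrix")
  nms <- colnames(X)
  if (is.null(nms) || any(!nzchar(nms)))
    stop_validation("all feature columns must be named")
  if (anyDuplicated(nms))
    stop_validation("duplicated feature names: ",
                    paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1L, ]
    stop_validation("missing value in feature '", nms[bad[2L]],
                    "', row ", bad[1L], " (no imputation is performed)")
  }
  y <- as.numeric(y)
  if (length(y) != nrow(X))
    stop_validation("length(y) must equal nrow(X)")
  if (anyNA(y) || !is_binary_values(y))
    stop_validation("outcome must contain only 0/1 values with no missing")
  auto <- vapply(seq_len(ncol(X)), function(j) is_binary_values(X[, j]),
                 logical(1))
  if (is.null(kinds)) {
    kinds <- ifelse(auto, "binary", "numeric")
  } else {
    kinds <- match.arg(kinds, c("binary", "numeric"), several.ok = TRUE)
    if (length(kinds) != ncol(X))
      stop_validation("kinds must have one entry per feature column")
    for (j in which(kinds == "binary" & !auto)) {
      bad_row <- which(!(X[, j] %in% c(0, 1)))[1L]
      stop_validation("column '", nms[j], "' is declared binary but has value ",
                      X[bad_row, j], " at row ", bad_row)
    }
  }
  structure(list(X = X, y = y, feature_names = nms, feature_kinds = kinds,
                 n = nrow(X), outcome_name = outcome_name),
            class = "como_data")
}

#' @export
print.como_data <- function(x, ...) {
  cat("<como_data> ", x$n, " records, ", length(x$feature_names),
      " features (", sum(x$feature_kinds == "binary"), " binary, ",
      sum(x$feature_kinds == "numeric"), " numeric), outcome rate ",
      sprintf("%.3f", mean(x$y)), "\n", sep = "")
  invisible(x)
}

#' Read a patient-level CSV into a modelling dataset
#'
#' Expects a plain UTF-8 CSV with a header row and "." decimals: one binary
#' outcome column plus a mix of 0/1 indicator columns and numeric
#' covariates. Columns whose observed values are all in \{0,1\} are
#' auto-flagged binary unless an explicit \code{binary_columns} list
#' overrides the guess (an integer count can masquerade as binary in small
#' samples). Missing values are rejected, not imputed.
#'
#' @param path CSV file path.
#' @param outcome_column name of the 0/1 outcome column.
#' @param binary_columns optional character vector naming exactly the
#'   feature columns to treat as binary; all others become numeric.
#' @return A [como_data] object; feature column order is preserved.
#' @export
read_dataset <- function(path, outcome_column, binary_columns = NULL) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (!outcome_column %in% names(df))
    stop_config("outcome column '", outcome_column, "' not present in ", path)
  y <- df[[outcome_column]]
  feats <- df[names(df) != outcome_column]
  for (nm in names(feats)) {
    if (!is.numeric(feats[[nm]]))
      stop_validation("column '", nm, "' is not numeric")
  }
  X <- as.matrix(feats)
  kinds <- NULL
  if (!is.null(binary_columns)) {
    missing_cols <- setdiff(binary_columns, colnames(X))
    if (length(missing_cols))
      stop_config("binary_columns not in file: ",
                  paste(missing_cols, collapse = ", "))
    kinds <- ifelse(colnames(X) %in% binary_columns, "binary", "numeric")
  }
  como_data(X, y, kinds = kinds, outcome_name = outcome_column)
}

#' Write a modelling dataset back to CSV
#'
#' @param ds a [como_data] object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "como_data"))
  df <- data.frame(ds$y, ds$X, check.names = FALSE)
  names(df)[1L] <- ds$outcome_name
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a design matrix for a list of terms
#'
#' Each [como_term] maps to one column: main effects copy the feature
#' column; products are elementwise \code{left * right}; the complement
#' terms are \code{left * (1 - right)} and \code{(1 - left) * right} and
#' are only defined when both members are binary indicators.
#'
#' @param ds a [como_data] object.
#' @param terms list of [como_term] descriptors.
#' @return Numeric matrix with one column per term, labelled by
#'   [term_label()].
#' @export
build_design <- function(ds, terms) {
  stopifnot(inherits(ds, "como_data"))
  if (inherits(terms, "como_term")) terms <- list(terms)
  if (!length(terms))
    return(matrix(numeric(0), nrow = ds$n, ncol = 0))
  kinds <- stats::setNames(ds$feature_kinds, ds$feature_names)
  cols <- lapply(terms, function(tm) {
    for (f in term_features(tm)) {
      if (!f %in% ds$feature_names)
        stop_validation("term references unknown feature '", f, "'")
    }
    l <- ds$X[, tm$left]
    switch(tm$role,
      MAIN = l,
      PRODUCT = l * ds$X[, tm$right],
      LEFT_ONLY = {
        check_binary_pair(tm, kinds)
        l * (1 - ds$X[, tm$right])
      },
      RIGHT_ONLY = {
        check_binary_pair(tm, kinds)
        (1 - l) * ds$X[, tm$right]
      })
  })
  out <- do.call(cbind, cols)
  colnames(out) <- term_labels(terms)
  out
}

check_binary_pair <- function(tm, kinds) {
  if (kinds[[tm$left]] != "binary" || kinds[[tm$right]] != "binary")
    stop_validation("complement term '", term_label(tm),
                    "' requires two binary features")
}

# subset rows of a dataset, keeping kinds
subset_data <- function(ds, idx) {
  Xs <- ds$X[idx, , drop = FALSE]
  structure(list(X = Xs, y = ds$y[idx],
                 feature_names = ds$feature_names,
                 feature_kinds = ds$feature_kinds,
                 n = nrow(Xs), outcome_name = ds$outcome_name),
            class = "como_data")
}
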