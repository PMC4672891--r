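# Step 2: complement-based Boolean feature expansion.

#' Expand screened interactions with Boolean complement features
#'
#' Turns an interaction set into the full list of model terms for the
#' final lasso: a MAIN descriptor for every retained main effect; then,
#' for each discovered pair, the PRODUCT term always, plus the two
#' complement terms \code{left = 1 AND right = 0} and
#' \code{left = 0 AND right = 1} when both members are binary diagnosis
#' indicators. Complements of numeric features are undefined, so pairs
#' involving a numeric member get product-only treatment (each skip is
#' reported via \code{message()}).
#'
#' The resulting design is deliberately collinear (\code{d_j = d_j d_k +
#' d_j (1 - d_k)}): pruning is the job of the step-3 lasso, which does not
#' enforce strong hierarchy.
#'
#' @param iset an \code{interaction_set} from [discover_interactions()].
#' @param ds the [como_data] the set was screened on (supplies feature
#'   kinds).
#' @return A list of unique [como_term] descriptors in deterministic
#'   order.
#' @export
expand_logical <- function(iset, ds) {
  stopifnot(inherits(iset, "interaction_set"), inherits(ds, "como_data"))
  bad <- setdiff(as.vector(iset$pairs), iset$main_effects)
  if (length(bad))
    stop_validation("hierarchy violated: pair members not in main effects: ",
                    paste(bad, collapse = ", "))
  kinds <- stats::setNames(ds$feature_kinds, ds$feature_names)
  # mains in dataset column order, then per-pair expansions in discovery order
  mains <- ds$feature_names[ds$feature_names %in% iset$main_effects]
  terms <- lapply(mains, main_term)
  if (nrow(iset$pairs)) {
    for (i in seq_len(nrow(iset$pairs))) {
      l <- iset$pairs[i, 1]
      r <- iset$pairs[i, 2]
      terms <- c(terms, list(product_term(l, r)))
      if (kinds[[l]] == "binary" && kinds[[r]] == "binary") {
        terms <- c(terms, list(left_only_term(l, r), right_only_term(l, r)))
      } else {
        message("skipping complement features for non-binary pair: ",
                l, " AND ", r)
      }
    }
  }
  terms[!duplicated(term_ids(terms))]
}
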