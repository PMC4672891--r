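#' Model term descriptors
#'
#' A fitted comorbidity model is a sparse set of interpretable terms. Each
#' term is one of four kinds: a main effect \code{x}; a product interaction
#' \code{x * z}; or one of the two Boolean complement ("comorbidity") terms
#' defined for binary diagnosis indicators only, \code{x * (1 - z)}
#' ("x present and z absent") and \code{(1 - x) * z} ("x absent and z
#' present"). Complement terms are what lets a model express a "switching"
#' pattern -- elevated risk when exactly one of two diagnoses is present --
#' which a plain product term cannot represent on its own.
#'
#' Product terms are stored with their member names in lexicographic order,
#' so \code{product_term(a, b)} and \code{product_term(b, a)} are identical.
#' Complement terms are order-sensitive by construction.
#'
#' @param name,left,right feature names.
#' @return An object of class \code{como_term} with fields \code{role}
#'   (one of \code{"MAIN"}, \code{"PRODUCT"}, \code{"LEFT_ONLY"},
#'   \code{"RIGHT_ONLY"}), \code{left} and \code{right}.
#' @examples
#' product_term("288.00", "204.00")
#' term_label(left_only_term("288.00", "204.00"))
#' @name como_term
NULL

new_term <- function(role, left, right = NA_character_) {
  stopifnot(is.character(left), length(left) == 1L, nzchar(left))
  structure(list(role = role, left = left, right = right),
            class = "como_term")
}

#' @rdname como_term
#' @export
main_term <- function(name) new_term("MAIN", name)

#' @rdname como_term
#' @export
product_term <- function(left, right) {
  stopifnot(left != right)
  nm <- sort(c(left, right))
  new_term("PRODUCT", nm[1L], nm[2L])
}

#' @rdname como_term
#' @export
left_only_term <- function(left, right) {
  stopifnot(left != right)
  new_term("LEFT_ONLY", left, right)
}

#' @rdname como_term
#' @export
right_only_term <- function(left, right) {
  stopifnot(left != right)
  new_term("RIGHT_ONLY", left, right)
}

#' Human-readable term labels
#'
#' Formats a term the way comorbidity tables print them: main effects by
#' their name, products as \code{"a AND b"}, and complement terms as
#' \code{"a = 1 AND b = 0"} / \code{"a = 0 AND b = 1"}.
#'
#' @param term a \code{como_term}.
#' @return A single string.
#' @export
term_label <- function(term) {
  stopifnot(inherits(term, "como_term"))
  switch(term$role,
    MAIN       = term$left,
    PRODUCT    = paste(term$left, "AND", term$right),
    LEFT_ONLY  = paste0(term$left, " = 1 AND ", term$right, " = 0"),
    RIGHT_ONLY = paste0(term$left, " = 0 AND ", term$right, " = 1"),
    stop_validation("unknown term role: ", term$role))
}

term_id <- function(term) paste(term$role, term$left, term$right, sep = "\r")

term_equal <- function(a, b) identical(term_id(a), term_id(b))

term_features <- function(term) {
  if (term$role == "MAIN") term$left else c(term$left, term$right)
}

#' @export
print.como_term <- function(x, ...) {
  cat("<term> ", term_label(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.como_term <- function(x, ...) term_label(x)

term_labels <- function(terms) vapply(terms, term_label, character(1))
term_ids <- function(terms) vapply(terms, term_id, character(1))
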