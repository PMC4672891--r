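# internal helpers

# evaluate expr with a private RNG state; the caller's stream is untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# fresh sub-seeds derived from the ambient stream (keep below 2^31)
draw_seeds <- function(k) sample.int(.Machine$integer.max - 1L, k)

stop_config <- function(...) {
  stop(structure(class = c("comologit_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("comologit_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_binary_values <- function(x) all(x %in% c(0, 1))

`%||%` <- function(a, b) if (is.null(a)) b else a

# stratified fold ids: every fold gets both classes where possible
stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

# stratified train/test split indices for a given training fraction
stratified_split <- function(y, fraction) {
  train <- logical(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_tr <- round(length(idx) * fraction)
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}
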