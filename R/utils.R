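#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded components (weight init, phantom sampling, shuffling)
#' never disturb global reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# derive a stream of sub-seeds from one master seed, kept below 2^31
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% .Machine$integer.max
}

stop_acunet <- function(..., class = "acunet_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x == as.integer(x) && x >= 1

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
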