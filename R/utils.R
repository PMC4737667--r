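# Internal error helpers. All package errors carry the class
# "fmridict_error" plus a specific subclass so callers (and tests) can
# distinguish shape errors from degenerate-data errors without string
# matching.

abort <- function(message, class) {
  stop(structure(
    class = c(class, "fmridict_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_shape <- function(message) abort(message, "fmridict_shape_error")
abort_insufficient <- function(message) abort(message, "fmridict_insufficient_data_error")
abort_value <- function(message) abort(message, "fmridict_value_error")
abort_placement <- function(message) abort(message, "fmridict_placement_error")

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so seeded internals never perturb the caller's
#' random stream. Every stochastic step in the package draws its
#' randomness through this helper, which is what makes whole-pipeline
#' runs reproducible from a single integer.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_value("seed must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) abort_value(sprintf("%s contains non-finite values", what))
  invisible(x)
}

# l2 norms of matrix columns
col_norms <- function(X) sqrt(colSums(X^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
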