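# Sparse coding: the l1-regularized least-squares fit of one signal (or
# all columns of the signal matrix) against the current dictionary,
#
#   min_a  1/2 ||s - D a||_2^2 + lambda ||a||_1 .
#
# The solver is cyclic coordinate descent on the covariance (Gram)
# formulation. It is deterministic: coordinates are visited in index
# order and convergence is declared when no coefficient moves by more
# than `tol` in a full sweep. All columns of a matrix are swept
# simultaneously (coordinate j is updated for every column in one BLAS
# call), which keeps columns mathematically independent — the update of
# column i never reads any other column.

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Core solver. D: m x k, S: m x n. Returns k x n coefficients.
# Columns whose largest coefficient change falls below `tol` are frozen
# and leave the working set; because columns never interact, each
# column's iterate sequence is exactly the one it would follow if solved
# alone, so freezing changes nothing but the cost.
cd_lasso <- function(D, S, lambda, tol = 1e-10, max_sweeps = 10000L) {
  G <- crossprod(D)              # k x k Gram matrix
  Cm <- crossprod(D, S)          # k x n correlations
  k <- ncol(D)
  n <- ncol(S)
  A <- matrix(0, k, n)
  g <- diag(G)
  active <- which(g > 1e-12)     # zero atoms never receive weight
  live <- seq_len(n)
  for (sweep in seq_len(max_sweeps)) {
    Al <- A[, live, drop = FALSE]
    Cl <- Cm[, live, drop = FALSE]
    dcol <- numeric(length(live))
    for (j in active) {
      r <- Cl[j, ] - drop(G[j, , drop = FALSE] %*% Al) + g[j] * Al[j, ]
      aj <- soft_threshold(r, lambda) / g[j]
      dcol <- pmax(dcol, abs(aj - Al[j, ]))
      Al[j, ] <- aj
    }
    A[, live] <- Al
    live <- live[dcol >= tol]
    if (length(live) == 0L) break
  }
  A
}

validate_coding_inputs <- function(D, m_signal, lambda) {
  if (is.null(dim(D)) || length(dim(D)) != 2L) abort_shape("D must be an m x k matrix")
  check_finite(D, "dictionary")
  if (nrow(D) != m_signal) {
    abort_shape(sprintf("signal has %d time points but dictionary has %d rows",
                        m_signal, nrow(D)))
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
    abort_value("lambda must be a single finite non-negative number")
  }
  if (lambda == 0) {
    # unpenalized least squares is only well-posed for full-column-rank D
    if (ncol(D) > nrow(D) || qr(D)$rank < ncol(D)) {
      abort_value("lambda = 0 requires k <= m and a full-column-rank dictionary")
    }
  }
  invisible(TRUE)
}

#' Sparse-code a single signal against a dictionary
#'
#' Solves the lasso problem `min 1/2 ||s - D a||^2 + lambda ||a||_1` by
#' cyclic coordinate descent. The returned coefficients satisfy the lasso
#' subgradient optimality conditions to solver tolerance and are
#' deterministic for fixed inputs.
#'
#' @param s length-m numeric signal.
#' @param D m x k dictionary matrix (atoms in columns).
#' @param lambda sparsity penalty (> 0; 0 is allowed only when `k <= m` and
#'   D has full column rank).
#' @param tol convergence threshold on the largest per-sweep coefficient
#'   change.
#' @param max_sweeps sweep cap.
#' @return an object of class `sparse_code`: `coefficients` (length k),
#'   `objective` (penalized loss at the solution) and `n_nonzero`
#'   (coefficients with `|a| > 1e-10`).
#' @export
sparse_code <- function(s, D, lambda, tol = 1e-10, max_sweeps = 10000L) {
  s <- as.numeric(s)
  check_finite(s, "signal")
  validate_coding_inputs(D, length(s), lambda)
  a <- cd_lasso(D, matrix(s, ncol = 1L), lambda, tol = tol, max_sweeps = max_sweeps)[, 1L]
  obj <- 0.5 * sum((s - D %*% a)^2) + lambda * sum(abs(a))
  structure(
    list(coefficients = a, objective = obj, n_nonzero = sum(abs(a) > 1e-10)),
    class = "sparse_code"
  )
}

#' @export
print.sparse_code <- function(x, ...) {
  cat(sprintf("<sparse_code> %d/%d nonzero, objective %.6g\n",
              x$n_nonzero, length(x$coefficients), x$objective))
  invisible(x)
}

#' Sparse-code every column of a signal matrix
#'
#' Column j of the result equals `sparse_code(S[, j], D, lambda)`; columns
#' are solved independently, so the result does not depend on any
#' processing order.
#'
#' @param S a `signal_matrix` or a plain m x n matrix.
#' @param D m x k dictionary.
#' @inheritParams sparse_code
#' @return the k x n coefficient matrix, with the penalty recorded in
#'   `attr(, "lambda")`.
#' @export
sparse_code_all <- function(S, D, lambda, tol = 1e-10, max_sweeps = 10000L) {
  X <- if (inherits(S, "signal_matrix")) S$data else as.matrix(S)
  check_finite(X, "signal matrix")
  validate_coding_inputs(D, nrow(X), lambda)
  A <- cd_lasso(D, X, lambda, tol = tol, max_sweeps = max_sweeps)
  attr(A, "lambda") <- lambda
  A
}

#' Penalized factorization objective
#'
#' The global loss the decomposition minimizes:
#' `1/2 ||S - D A||_F^2 + lambda * sum(|A|)`. Equals the sum over columns
#' of the per-signal sparse-coding objectives.
#'
#' @inheritParams sparse_code_all
#' @param A k x n coefficient matrix.
#' @return a single number.
#' @export
factorization_objective <- function(S, D, A, lambda) {
  X <- if (inherits(S, "signal_matrix")) S$data else as.matrix(S)
  0.5 * sum((X - D %*% A)^2) + lambda * sum(abs(A))
}
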