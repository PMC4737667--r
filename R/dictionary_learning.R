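# Online (mini-batch) dictionary learning.
#
# The signal matrix S (m time points x n voxels) is factorized as
# S ~ D A with D in the constraint set C = { D : ||d_j||_2 <= 1 for all j }
# and A sparse, by alternating mini-batch sparse coding with block
# coordinate-descent dictionary updates driven by the accumulated
# sufficient statistics A_t = sum a a^T and B_t = sum s a^T. One atom is
# one network's temporal pattern; the matching row of the coefficient
# matrix is its spatial loading over voxels.

#' Configuration for online dictionary learning
#'
#' @param k number of atoms. The decomposition is intended to be
#'   over-complete (`k > m`) while still small relative to the voxel count
#'   (`k << n`); the regime is checked at fit time and warned about, not
#'   enforced. Default 400 atoms, a scale at which whole-brain recordings
#'   resolve into several hundred components.
#' @param lambda sparsity penalty. `NULL` (default) selects
#'   `median(column l2 norm) / sqrt(m)` at fit time — a dimension-aware
#'   default that is about 1 for unit-variance columns.
#' @param batch_size columns per mini-batch.
#' @param n_epochs full passes over the columns. `0` returns the initial
#'   dictionary and its codes.
#' @param seed RNG seed controlling initialization and the per-epoch
#'   column shuffle.
#' @param init initialization method; currently `"sample"` (atoms drawn
#'   from data columns).
#' @return an object of class `odl_config`.
#' @export
odl_config <- function(k = 400L, lambda = NULL, batch_size = 256L,
                       n_epochs = 5L, seed = 1L, init = "sample") {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort_value("k must be a positive integer")
  if (!is.null(lambda) &&
      (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) || lambda < 0)) {
    abort_value("lambda must be NULL or a single non-negative number")
  }
  batch_size <- as.integer(batch_size)
  if (is.na(batch_size) || batch_size < 1L) abort_value("batch_size must be >= 1")
  n_epochs <- as.integer(n_epochs)
  if (is.na(n_epochs) || n_epochs < 0L) abort_value("n_epochs must be >= 0")
  init <- match.arg(init, "sample")
  structure(
    list(k = k, lambda = lambda, batch_size = batch_size,
         n_epochs = n_epochs, seed = as.integer(seed), init = init),
    class = "odl_config"
  )
}

default_lambda <- function(X) median(col_norms(X)) / sqrt(nrow(X))

signal_data <- function(S) {
  if (inherits(S, "signal_matrix")) S$data else as.matrix(S)
}

#' Initialize a dictionary from data columns
#'
#' Atoms are `k` distinct columns of S, each projected onto the unit l2
#' ball. A candidate pool of `min(n, 5k)` columns is drawn without
#' replacement under `seed`; from it, columns are selected greedily so
#' that each new atom has the smallest maximum |correlation| with the
#' atoms already chosen (maximin selection, in the spirit of k-means++
#' seeding). Starting from mutually decorrelated atoms makes it far less
#' likely that two atoms lock onto the same underlying network while
#' another goes unrepresented. Deterministic for a fixed seed.
#'
#' @param S `signal_matrix` or plain matrix with at least `k` columns.
#' @param k atom count.
#' @param seed RNG seed; the same seed always yields the same dictionary.
#' @return an m x k matrix.
#' @export
init_dictionary <- function(S, k, seed = 1L) {
  X <- signal_data(S)
  n <- ncol(X)
  if (n < k) abort_insufficient(sprintf("need at least k = %d columns, have %d", k, n))
  pool <- with_seed(seed, sample.int(n, min(n, max(5L * k, k))))
  Xp <- X[, pool, drop = FALSE]
  nrm <- col_norms(Xp)
  U <- sweep(Xp, 2L, pmax(nrm, 1e-12), "/")
  chosen <- integer(k)
  # exclude zero-norm candidates unless nothing else remains
  maxcor <- ifelse(nrm > 1e-12, 0, Inf)
  first <- which(maxcor == 0)[1]
  if (is.na(first)) first <- 1L
  chosen[1] <- first
  maxcor <- pmax(maxcor, abs(drop(crossprod(U, U[, first]))))
  maxcor[first] <- Inf
  for (j in seq_len(k)[-1]) {
    pick <- which.min(maxcor)
    chosen[j] <- pick
    maxcor <- pmax(maxcor, abs(drop(crossprod(U, U[, pick]))))
    maxcor[pick] <- Inf
  }
  D <- Xp[, chosen, drop = FALSE]
  D <- sweep(D, 2L, pmax(1, col_norms(D)), "/")
  dimnames(D) <- NULL
  D
}

#' One block coordinate-descent pass over the dictionary atoms
#'
#' For each atom j with accumulated usage `A[j, j] > eps`:
#' `u_j = d_j + (b_j - D a_j) / A[j, j]`, then `d_j <- u_j / max(1, ||u_j||)`,
#' i.e. a gradient step on the quadratic surrogate followed by projection
#' onto the unit ball. Unused atoms (`A[j, j] <= eps`) are left unchanged.
#' The surrogate objective never increases under this pass.
#'
#' @param D m x k dictionary.
#' @param stats list with `A` (k x k), `B` (m x k) and `t` (samples seen),
#'   as accumulated by [learn_dictionary()].
#' @param eps usage threshold guarding the division.
#' @return the updated m x k dictionary.
#' @export
update_dictionary <- function(D, stats, eps = 1e-12) {
  if (!all(is.finite(stats$A)) || !all(is.finite(stats$B))) {
    abort_value("surrogate statistics contain non-finite values")
  }
  if (stats$t < 1) abort_value("no samples accumulated yet (stats$t < 1)")
  A <- stats$A
  B <- stats$B
  for (j in seq_len(ncol(D))) {
    ajj <- A[j, j]
    if (ajj <= eps) next
    u <- D[, j] + (B[, j] - D %*% A[, j]) / ajj
    D[, j] <- u / max(1, sqrt(sum(u^2)))
  }
  D
}

#' Surrogate objective driven by the sufficient statistics
#'
#' `1/2 tr(D^T D A) - tr(D^T B)`, the dictionary-dependent part of the
#' quadratic surrogate that [update_dictionary()] descends. Exposed so the
#' descent property can be verified directly.
#'
#' @inheritParams update_dictionary
#' @return a single number.
#' @export
surrogate_objective <- function(D, stats) {
  0.5 * sum(crossprod(D) * stats$A) - sum(D * stats$B)
}

#' Learn a dictionary by online mini-batch alternation
#'
#' Iterates over seeded-shuffled mini-batches of voxel columns: each batch
#' is sparse-coded against the current dictionary, the sufficient
#' statistics are accumulated, and one block coordinate-descent pass
#' updates the atoms under the unit-ball constraint. Atoms still unused
#' after a full epoch are replaced by the worst-reconstructed signal of
#' the last batch (renormalized). After the final epoch the whole matrix
#' is re-coded against the final dictionary to produce the coefficient
#' matrix.
#'
#' The trajectory is a deterministic function of `(S, cfg)`: two calls
#' with the same inputs return identical results.
#'
#' @param S `signal_matrix` (normalized) or plain m x n matrix.
#' @param cfg an [odl_config()].
#' @return an object of class `odl_fit`: `dictionary` (m x k), `alpha`
#'   (k x n), `lambda`, `objective` (final penalized loss),
#'   `epoch_objectives` (full-data objective at initialization and after
#'   each epoch), `atom_norm_trace` (max atom norm after every dictionary
#'   update), `config`, `m`, `n`.
#' @export
learn_dictionary <- function(S, cfg = odl_config()) {
  X <- signal_data(S)
  check_finite(X, "signal matrix")
  m <- nrow(X)
  n <- ncol(X)
  k <- cfg$k
  if (k > n) abort_insufficient(sprintf("k = %d exceeds the number of columns (%d)", k, n))
  if (k <= m || k > n / 10) {
    warning(sprintf(paste0("k = %d is outside the recommended over-complete regime ",
                           "(k > m = %d and k << n = %d)"), k, m, n), call. = FALSE)
  }
  lambda <- cfg$lambda %||% default_lambda(X)

  D <- init_dictionary(X, k, cfg$seed)
  alpha <- sparse_code_all(X, D, lambda)
  epoch_obj <- factorization_objective(X, D, alpha, lambda)
  norm_trace <- numeric(0)

  stats <- list(A = matrix(0, k, k), B = matrix(0, m, k), t = 0L)
  if (cfg$n_epochs > 0L) {
    for (epoch in seq_len(cfg$n_epochs)) {
      ord <- with_seed(cfg$seed + epoch, sample.int(n))
      starts <- seq(1L, n, by = cfg$batch_size)
      last_Sb <- NULL
      last_Ab <- NULL
      for (s0 in starts) {
        b <- ord[s0:min(s0 + cfg$batch_size - 1L, n)]
        Sb <- X[, b, drop = FALSE]
        Ab <- cd_lasso(D, Sb, lambda)
        stats$A <- stats$A + tcrossprod(Ab)
        stats$B <- stats$B + tcrossprod(Sb, Ab)
        stats$t <- stats$t + length(b)
        D <- update_dictionary(D, stats)
        norm_trace <- c(norm_trace, max(col_norms(D)))
        last_Sb <- Sb
        last_Ab <- Ab
      }
      # atom housekeeping: atoms that attracted no weight in any batch so
      # far (dead) or that duplicate an earlier atom (|cos| > 0.99 —
      # redundant copies starve other structure of representation) are
      # replaced by the hardest-to-reconstruct recent signals
      dead <- which(diag(stats$A) <= 1e-12)
      Dn <- sweep(D, 2L, pmax(col_norms(D), 1e-12), "/")
      Gn <- abs(crossprod(Dn))
      dup <- which(vapply(seq_len(k), function(j) {
        j > 1L && any(Gn[seq_len(j - 1L), j] > 0.99)
      }, logical(1)))
      recycle <- union(dead, dup)
      if (length(recycle) > 0L) {
        R <- last_Sb - D %*% last_Ab
        worst <- order(colSums(R^2), decreasing = TRUE)
        for (i in seq_along(recycle)) {
          if (i > length(worst)) break
          u <- last_Sb[, worst[i]]
          nu <- sqrt(sum(u^2))
          if (nu > 0) D[, recycle[i]] <- u / nu
        }
      }
      alpha <- sparse_code_all(X, D, lambda)
      epoch_obj <- c(epoch_obj, factorization_objective(X, D, alpha, lambda))
    }
  }

  structure(
    list(dictionary = D,
         alpha = alpha,
         lambda = lambda,
         objective = epoch_obj[length(epoch_obj)],
         epoch_objectives = epoch_obj,
         atom_norm_trace = norm_trace,
         config = cfg,
         m = m, n = n),
    class = "odl_fit"
  )
}

#' @export
print.odl_fit <- function(x, ...) {
  cat(sprintf("<odl_fit> %d atoms over %d time points, %d voxels; lambda %.4g; objective %.6g\n",
              ncol(x$dictionary), x$m, x$n, x$lambda, x$objective))
  invisible(x)
}
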