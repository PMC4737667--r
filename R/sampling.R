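# Voxel-sampling speedup: train the dictionary on a random subset of
# voxel columns, then sparse-code every voxel against the learned
# dictionary so the spatial maps still cover the whole brain. At
# ratio = 1 the path reduces exactly (bitwise) to plain learning.

#' Configuration for column sampling
#'
#' @param ratio fraction of voxel columns used for dictionary training,
#'   in (0, 1]. `ratio = 1` reproduces the unsampled path exactly.
#' @param seed RNG seed for the subset draw.
#' @param strategy sampling strategy; currently `"uniform"` (uniform
#'   without replacement).
#' @return an object of class `sampling_config`.
#' @export
sampling_config <- function(ratio = 1, seed = 1L, strategy = "uniform") {
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) ||
      ratio <= 0 || ratio > 1) {
    abort_value("ratio must be in (0, 1]")
  }
  strategy <- match.arg(strategy, "uniform")
  structure(list(ratio = ratio, seed = as.integer(seed), strategy = strategy),
            class = "sampling_config")
}

#' Draw a training subset of voxel columns
#'
#' Uniform random subset of `round(ratio * n)` columns without
#' replacement, deterministic under the config seed, returned in
#' ascending column order. `ratio = 1` returns the identity subset
#' without touching the RNG.
#'
#' @param S a `signal_matrix` (or plain matrix).
#' @param cfg a [sampling_config()].
#' @return a list with `subset` (the column-subset `signal_matrix` or
#'   matrix) and `indices` (1-based positions of the kept columns in S).
#' @export
sample_columns <- function(S, cfg) {
  X <- signal_data(S)
  n <- ncol(X)
  size <- round(cfg$ratio * n)
  if (size < 1L) abort_insufficient("sampling ratio leaves no columns")
  idx <- if (cfg$ratio == 1) seq_len(n) else with_seed(cfg$seed, sort(sample.int(n, size)))
  subset <- if (inherits(S, "signal_matrix")) {
    out <- S
    out$data <- S$data[, idx, drop = FALSE]
    out$voxel_index <- S$voxel_index[idx, , drop = FALSE]
    out
  } else {
    X[, idx, drop = FALSE]
  }
  list(subset = subset, indices = idx)
}

#' Learn a dictionary on sampled columns, code all columns
#'
#' Dictionary training sees only the sampled subset; the final
#' coefficient matrix is computed on the full signal matrix so every
#' voxel receives a spatial loading. With `ratio = 1` the result is
#' bitwise identical to [learn_dictionary()].
#'
#' @param S `signal_matrix` or plain m x n matrix.
#' @param odl_cfg an [odl_config()].
#' @param s_cfg a [sampling_config()].
#' @return an `odl_fit` whose `alpha` and `objective` refer to the full
#'   matrix, with the subset recorded in `$sampling` (config and chosen
#'   indices, for provenance).
#' @export
learn_dictionary_sampled <- function(S, odl_cfg = odl_config(), s_cfg = sampling_config()) {
  sc <- sample_columns(S, s_cfg)
  if (length(sc$indices) < odl_cfg$k) {
    abort_insufficient(sprintf(
      "sampled subset has %d columns but k = %d atoms are requested",
      length(sc$indices), odl_cfg$k))
  }
  fit <- learn_dictionary(sc$subset, odl_cfg)
  X <- signal_data(S)
  fit$alpha <- sparse_code_all(X, fit$dictionary, fit$lambda)
  fit$objective <- factorization_objective(X, fit$dictionary, fit$alpha, fit$lambda)
  fit$n <- ncol(X)
  fit$sampling <- list(config = s_cfg, indices = sc$indices)
  fit
}
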