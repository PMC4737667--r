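# Independent brute-force lasso oracle: enumerate every support set and
# sign pattern, solve the stationarity system in closed form, keep the
# candidates whose signs and off-support subgradients are consistent,
# and return the best. Exact (up to linear solves) for k <= ~8; never
# shares code with the package's coordinate-descent solver.
lasso_brute <- function(D, s, lambda) {
  k <- ncol(D)
  G <- crossprod(D)
  cvec <- drop(crossprod(D, s))
  best <- NULL
  if (all(abs(cvec) <= lambda + 1e-9)) {
    best <- list(coefficients = rep(0, k), objective = 0.5 * sum(s^2))
  }
  supports <- lapply(1:(2^k - 1), function(bits) which(bitwAnd(bits, 2^(0:(k - 1))) > 0))
  for (A in supports) {
    signs_grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(A))))
    for (r in seq_len(nrow(signs_grid))) {
      sg <- signs_grid[r, ]
      GA <- G[A, A, drop = FALSE]
      if (abs(det(GA)) < 1e-12) next
      aA <- solve(GA, cvec[A] - lambda * sg)
      if (any(sign(aA) != sg)) next
      resid_corr <- cvec - G[, A, drop = FALSE] %*% aA
      out <- setdiff(seq_len(k), A)
      if (length(out) > 0 && any(abs(resid_corr[out]) > lambda + 1e-9)) next
      a <- rep(0, k)
      a[A] <- aA
      obj <- 0.5 * sum((s - D %*% a)^2) + lambda * sum(abs(a))
      if (is.null(best) || obj < best$objective) {
        best <- list(coefficients = a, objective = obj)
      }
    }
  }
  best
}

# KKT residual of a lasso solution: max violation of the subgradient
# optimality conditions
lasso_kkt_violation <- function(D, s, a, lambda) {
  g <- drop(crossprod(D, s - D %*% a))
  nz <- abs(a) > 1e-10
  v_zero <- if (any(!nz)) max(abs(g[!nz])) - lambda else -Inf
  v_nonzero <- if (any(nz)) max(abs(g[nz] - lambda * sign(a[nz]))) else 0
  max(v_zero, v_nonzero)
}

# greedy max-|cosine| matching of learned atoms to ground-truth atoms
cosine_match <- function(D_learned, D_true) {
  Cn <- abs(crossprod(
    sweep(D_learned, 2, sqrt(colSums(D_learned^2)), "/"),
    sweep(D_true, 2, sqrt(colSums(D_true^2)), "/")
  ))
  out <- numeric(ncol(D_true))
  for (i in seq_len(ncol(D_true))) {
    w <- which(Cn == max(Cn), arr.ind = TRUE)[1, ]
    out[w[2]] <- Cn[w[1], w[2]]
    Cn[w[1], ] <- -1
    Cn[, w[2]] <- -1
  }
  out
}
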