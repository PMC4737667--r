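test_that("initialization draws data columns, projected to the unit ball", {
  X <- with_seed(2, matrix(rnorm(10 * 100), 10, 100))
  D <- init_dictionary(X, 5, seed = 9)
  nrm <- sqrt(colSums(D^2))
  expect_true(all(nrm > 0 & nrm <= 1 + 1e-12))
  # every atom is a rescaled data column
  for (j in 1:5) {
    match_col <- apply(X, 2, function(x) {
      isTRUE(all.equal(x / max(1, sqrt(sum(x^2))), D[, j], tolerance = 1e-12))
    })
    expect_true(any(match_col))
  }
  expect_identical(D, init_dictionary(X, 5, seed = 9))
  expect_false(identical(D, init_dictionary(X, 5, seed = 10)))
  # k = n is a column permutation of the projected data
  Xs <- X[, 1:6]
  D6 <- init_dictionary(Xs, 6, seed = 1)
  proj <- sweep(Xs, 2, pmax(1, sqrt(colSums(Xs^2))), "/")
  expect_equal(sort(colSums(D6)), sort(colSums(proj)), tolerance = 1e-12)
  expect_error(init_dictionary(Xs, 7), class = "fmridict_insufficient_data_error")
})

test_that("exact self-codes of an orthonormal dictionary are a fixed point", {
  D <- qr.Q(qr(with_seed(3, matrix(rnorm(6 * 3), 6, 3))))
  # S = D, codes = I (lambda -> 0 limit): A = I, B = S
  stats <- list(A = diag(3), B = D, t = 3L)
  D2 <- update_dictionary(D, stats)
  expect_equal(D2, D, tolerance = 1e-6)
})

test_that("unused atoms are left untouched by the update", {
  D <- random_dictionary(5, 4, seed = 4)
  stats <- list(A = diag(c(1, 0, 1, 1)), B = with_seed(5, matrix(rnorm(20), 5, 4)), t = 3L)
  D2 <- update_dictionary(D, stats)
  expect_identical(D2[, 2], D[, 2])
  expect_false(identical(D2[, 1], D[, 1]))
})

test_that("the update never increases the surrogate objective", {
  set.seed(6)
  for (trial in 1:5) {
    m <- 8; k <- 5; nb <- 30
    D <- random_dictionary(m, k, seed = trial)
    Sb <- matrix(rnorm(m * nb), m, nb)
    Ab <- sparse_code_all(Sb, D, 0.1)
    stats <- list(A = tcrossprod(Ab), B = tcrossprod(Sb, Ab), t = nb)
    before <- surrogate_objective(D, stats)
    D2 <- update_dictionary(D, stats)
    expect_lte(surrogate_objective(D2, stats), before + 1e-8)
    expect_true(all(sqrt(colSums(D2^2)) <= 1 + 1e-10))
  }
})

test_that("update rejects corrupt statistics", {
  D <- random_dictionary(5, 3)
  expect_error(update_dictionary(D, list(A = diag(3) * NA, B = matrix(0, 5, 3), t = 1L)),
               class = "fmridict_value_error")
  expect_error(update_dictionary(D, list(A = diag(3), B = matrix(0, 5, 3), t = 0L)),
               class = "fmridict_value_error")
})

test_that("planted temporal atoms are recovered up to sign and permutation", {
  set.seed(10)
  m <- 24; k0 <- 4; n <- 300
  D0 <- qr.Q(qr(matrix(rnorm(m * k0), m, k0)))   # well-separated atoms
  memb <- sample(k0, n, replace = TRUE)
  A0 <- matrix(0, k0, n)
  for (j in seq_len(n)) A0[memb[j], j] <- runif(1, 2, 4)
  S <- D0 %*% A0 + 0.02 * matrix(rnorm(m * n), m, n)
  fit <- suppressWarnings(
    learn_dictionary(S, odl_config(k = k0, batch_size = 50,
                                   n_epochs = 10, seed = 2)))
  cos <- cosine_match(fit$dictionary, D0)
  expect_true(all(cos >= 0.95))
})

test_that("n_epochs = 0 returns the initial dictionary with its codes", {
  fx <- tiny_subject()
  cfg <- odl_config(k = 8, n_epochs = 0, seed = 3)
  fit <- suppressWarnings(learn_dictionary(fx$S, cfg))
  expect_identical(fit$dictionary, init_dictionary(fx$S, 8, seed = 3))
  expect_identical(fit$alpha,
                   sparse_code_all(fx$S, fit$dictionary, fit$lambda))
  expect_length(fit$epoch_objectives, 1)
})

test_that("training is deterministic under a fixed seed", {
  fx <- tiny_subject()
  cfg <- odl_config(k = 8, n_epochs = 2, seed = 5)
  f1 <- suppressWarnings(learn_dictionary(fx$S, cfg))
  f2 <- suppressWarnings(learn_dictionary(fx$S, cfg))
  expect_identical(f1$dictionary, f2$dictionary)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$epoch_objectives, f2$epoch_objectives)
})

test_that("atom norms stay in the unit ball and objectives descend", {
  fx <- tiny_subject()
  fit <- suppressWarnings(learn_dictionary(fx$S, odl_config(k = 8, n_epochs = 4, seed = 1)))
  expect_true(all(fit$atom_norm_trace <= 1 + 1e-10))
  obj <- fit$epoch_objectives
  expect_true(all(diff(obj) <= 0.01 * obj[-length(obj)]))
  # trained atoms are all live on non-degenerate data
  expect_true(all(sqrt(colSums(fit$dictionary^2)) > 0))
})

test_that("the over-completeness regime is advisory, not enforced", {
  X <- with_seed(8, matrix(rnorm(20 * 50), 20, 50))
  expect_warning(learn_dictionary(X, odl_config(k = 10, n_epochs = 1)),
                 "over-complete")
})
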