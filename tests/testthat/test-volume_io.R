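test_that("load_fmri builds an m x n matrix from a 4D image and mask", {
  dims <- c(4, 4, 4)
  m <- 10
  arr <- with_seed(5, array(rnorm(prod(dims) * m), c(dims, m)))
  mask_arr <- array(FALSE, dims)
  mask_arr[with_seed(6, sample(prod(dims), 20))] <- TRUE
  f_img <- tempfile(fileext = ".nii")
  f_msk <- tempfile(fileext = ".nii")
  write_volume(arr, f_img)
  write_volume(mask_arr * 1, f_msk)

  S <- load_fmri(f_img, f_msk)
  expect_equal(nrow(S$data), 10)
  expect_equal(ncol(S$data), 20)
  expect_equal(S$mask$n_voxels, 20)

  # column j is the time series at voxel_index[j]
  j <- 7
  co <- S$voxel_index[j, ] + 1L
  expect_identical(S$data[, j], arr[co[1], co[2], co[3], ])

  # voxel ordering is stable across repeated loads
  S2 <- load_fmri(f_img, f_msk)
  expect_identical(S$voxel_index, S2$voxel_index)
  expect_identical(S$data, S2$data)
})

test_that("degenerate inputs are rejected with typed errors", {
  expect_error(brain_mask(array(FALSE, c(3, 3, 3))),
               class = "fmridict_insufficient_data_error")
  mask <- brain_mask(array(TRUE, c(3, 3, 3)))
  expect_error(as_signal_matrix(array(0, c(4, 4, 4, 5)), mask),
               class = "fmridict_shape_error")
  expect_error(as_signal_matrix(array(0, c(3, 3, 3, 1)), mask),
               class = "fmridict_insufficient_data_error")
})

test_that("a generated subject round-trips through NIfTI exactly", {
  fx <- tiny_subject()
  f <- tempfile(fileext = ".nii")
  write_volume(fx$subject$data, f, mask = fx$templates$mask,
               tr_seconds = fx$spec$tr_seconds)
  f_msk <- tempfile(fileext = ".nii")
  write_volume(fx$templates$mask$grid * 1, f_msk)
  S_disk <- load_fmri(f, f_msk)
  S_mem <- as_signal_matrix(fx$subject$data, fx$templates$mask)
  expect_identical(S_disk$data, S_mem$data)
  expect_identical(S_disk$voxel_index, S_mem$voxel_index)
})

test_that("normalization detrends, standardizes and drops degenerate columns", {
  mask <- brain_mask(array(TRUE, c(2, 2, 1)))
  arr <- array(0, c(2, 2, 1, 4))
  ts_list <- list(c(5, 5, 5, 5),      # constant -> dropped
                  c(1, 2, 3, 4),      # pure linear trend -> dropped
                  c(1, 3, 2, 4),      # survives
                  c(2, 0, 5, 1))      # survives
  idx <- which(array(TRUE, c(2, 2, 1)))
  for (j in seq_along(ts_list)) {
    co <- arrayInd(idx[j], c(2, 2, 1))
    arr[co[1], co[2], co[3], ] <- ts_list[[j]]
  }
  S <- normalize_signals(as_signal_matrix(arr, mask))
  expect_equal(ncol(S$data), 2)
  expect_equal(sort(S$dropped), c(1, 2))
  expect_lt(max(abs(colMeans(S$data))), 1e-8)
  expect_equal(apply(S$data, 2, stats::var), c(1, 1), tolerance = 1e-8)

  # column [1,3,2,4]: recompute the moments directly from the detrend model
  y <- c(1, 3, 2, 4)
  r <- residuals(lm(y ~ seq_along(y)))
  expect_equal(S$data[, 1], unname(r / sd(r)), tolerance = 1e-8)

  # idempotence
  S2 <- normalize_signals(S)
  expect_equal(S2$data, S$data, tolerance = 1e-8)

  # all-degenerate input errors
  flat <- array(rep(c(1, 2, 3, 4), each = 4), c(2, 2, 1, 4))
  expect_error(normalize_signals(as_signal_matrix(flat, mask)),
               class = "fmridict_insufficient_data_error")
})

test_that("map_row_to_volume inverts the flattening exactly", {
  fx <- tiny_subject()
  S <- fx$S
  mask <- fx$templates$mask

  v <- with_seed(3, rnorm(ncol(S$data)))
  vol <- map_row_to_volume(v, mask, S$voxel_index)
  expect_identical(flatten_volume(vol, S$voxel_index), v)

  full_index <- arrayInd(which(mask$grid), dim(mask$grid)) - 1L
  ones <- map_row_to_volume(rep(1, mask$n_voxels), mask, full_index)
  expect_identical(ones, mask$grid * 1)

  v0 <- rep(0, ncol(S$data)); v0[4] <- 2.5
  vol0 <- map_row_to_volume(v0, mask, S$voxel_index)
  expect_equal(sum(vol0 != 0), 1)
  co <- S$voxel_index[4, ] + 1L
  expect_equal(vol0[co[1], co[2], co[3]], 2.5)

  expect_error(map_row_to_volume(1:3, mask, S$voxel_index),
               class = "fmridict_shape_error")
})
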