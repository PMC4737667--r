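# NIfTI input/output and signal-matrix construction.
#
# The whole-brain data of one subject live in an m x n matrix S: row i is
# the brain at time point i, column j is the BOLD time series of one voxel.
# The voxel <-> column correspondence is carried explicitly (voxel_index)
# so that mapping coefficient rows back onto the grid never relies on a
# flattening convention being remembered elsewhere.

#' Construct a brain mask
#'
#' A mask is the set of voxels that constitute "the whole brain" for the
#' analysis: signal-matrix columns exist only for in-mask voxels.
#'
#' @param grid 3D logical (or coercible) array; `TRUE` marks in-brain voxels.
#' @param affine 4x4 voxel-to-world matrix. Carried through to every map
#'   written back to disk; never interpreted by the package itself.
#' @param reference optional `niftiImage` whose header geometry is reused
#'   when writing derived volumes.
#' @return an object of class `brain_mask` with fields `grid`, `affine`,
#'   `n_voxels` and `reference`.
#' @export
brain_mask <- function(grid, affine = diag(4), reference = NULL) {
  d <- dim(grid)
  if (is.null(d) || length(d) != 3L) abort_shape("mask grid must be a 3D array")
  grid <- array(as.logical(grid) & !is.na(grid), dim = d)
  n <- sum(grid)
  if (n < 1L) abort_insufficient("mask contains no voxels")
  affine <- unclass(affine)
  if (is.null(dim(affine)) || !all(dim(affine) == c(4L, 4L))) {
    abort_shape("affine must be a 4x4 matrix")
  }
  if (abs(det(affine)) < 1e-12) abort_value("affine must be invertible")
  structure(
    list(grid = grid, affine = matrix(as.numeric(affine), 4, 4),
         n_voxels = n, reference = reference),
    class = "brain_mask"
  )
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> grid %s, %d voxels\n",
              paste(dim(x$grid), collapse = "x"), x$n_voxels))
  invisible(x)
}

# 0-based grid coordinates of in-mask voxels, raster order (x fastest).
# which() on an array enumerates linear indices in exactly that order.
mask_voxel_index <- function(mask) {
  arrayInd(which(mask$grid), dim(mask$grid)) - 1L
}

#' Build a signal matrix from an in-memory 4D array
#'
#' @param x 4D numeric array (x, y, z, time).
#' @param mask a [brain_mask()] on the same grid.
#' @param tr_seconds repetition time in seconds (metadata only).
#' @return an object of class `signal_matrix`: `data` (m x n matrix),
#'   `voxel_index` (n x 3 integer matrix of 0-based grid coordinates,
#'   row j locating column j of `data`), `tr_seconds`, `mask`,
#'   `normalized` flag and `dropped` (columns removed by normalization).
#' @export
as_signal_matrix <- function(x, mask, tr_seconds = NA_real_) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L) abort_shape("expected a 4D array (x, y, z, time)")
  if (!inherits(mask, "brain_mask")) abort_value("mask must be a brain_mask")
  if (!all(d[1:3] == dim(mask$grid))) {
    abort_shape(sprintf("image grid %s does not match mask grid %s",
                        paste(d[1:3], collapse = "x"),
                        paste(dim(mask$grid), collapse = "x")))
  }
  m <- d[4]
  if (m < 2L) abort_insufficient("need at least 2 time points")
  lin <- which(mask$grid)
  flat <- matrix(as.numeric(x), prod(d[1:3]), m)
  data <- t(flat[lin, , drop = FALSE])
  structure(
    list(data = data,
         voxel_index = mask_voxel_index(mask),
         tr_seconds = as.numeric(tr_seconds),
         mask = mask,
         normalized = FALSE,
         dropped = integer(0)),
    class = "signal_matrix"
  )
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d time points x %d voxels%s\n",
              nrow(x$data), ncol(x$data),
              if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Load a 4D fMRI volume as a signal matrix
#'
#' Reads a 4D NIfTI image and a 3D mask, checks that they share a grid, and
#' aggregates the in-mask voxel time series into the m x n signal matrix.
#' Column order is raster order over the grid with the first axis varying
#' fastest, and is identical across repeated loads of the same files.
#'
#' @param path 4D NIfTI file (.nii or .nii.gz).
#' @param mask_path 3D NIfTI mask file; any nonzero voxel is in-mask.
#' @return a `signal_matrix`.
#' @export
load_fmri <- function(path, mask_path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort_value(sprintf("cannot read NIfTI '%s': %s",
                                                          path, conditionMessage(e))))
  mk <- tryCatch(RNifti::readNifti(mask_path),
                 error = function(e) abort_value(sprintf("cannot read NIfTI '%s': %s",
                                                         mask_path, conditionMessage(e))))
  dm <- dim(mk)
  if (length(dm) == 4L && dm[4] == 1L) { # tolerate degenerate 4th mask dim
    mk_arr <- array(as.numeric(mk), dm[1:3])
  } else if (length(dm) == 3L) {
    mk_arr <- array(as.numeric(mk), dm)
  } else {
    abort_shape("mask must be a 3D volume")
  }
  mask <- brain_mask(mk_arr != 0, affine = RNifti::xform(mk), reference = mk)
  if (length(dim(img)) != 4L) abort_shape("fMRI image must be 4D")
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4L) pd[4] else NA_real_
  as_signal_matrix(array(as.numeric(img), dim(img)), mask, tr_seconds = tr)
}

#' Detrend and standardize every voxel time series
#'
#' Removes the best-fit line from each column (the in-package analog of
#' scanner drift removal; heavier preprocessing is assumed to have happened
#' upstream) and scales each column to zero mean and unit variance. Columns
#' whose post-detrend variance falls below `var_tol` carry no usable signal
#' and are removed; their positions are recorded in `$dropped` and their
#' `voxel_index` rows deleted. Idempotent up to floating-point error.
#'
#' @param S a `signal_matrix`.
#' @param var_tol variance threshold below which a column is dropped.
#' @return the normalized `signal_matrix`.
#' @export
normalize_signals <- function(S, var_tol = 1e-12) {
  if (!inherits(S, "signal_matrix")) abort_value("S must be a signal_matrix")
  X <- S$data
  m <- nrow(X)
  if (m < 2L) abort_insufficient("need at least 2 time points to normalize")
  tt <- cbind(1, seq_len(m))
  Q <- qr.Q(qr(tt))
  X <- X - Q %*% crossprod(Q, X)      # residual of per-column linear fit
  v <- colSums(X^2) / (m - 1)
  keep <- v >= var_tol
  if (!any(keep)) abort_insufficient("all voxel time series are constant or purely linear")
  dropped <- which(!keep)
  X <- X[, keep, drop = FALSE]
  X <- sweep(X, 2L, sqrt(v[keep]), "/")
  out <- S
  out$data <- X
  out$voxel_index <- S$voxel_index[keep, , drop = FALSE]
  out$dropped <- c(S$dropped, dropped)
  out$normalized <- TRUE
  out
}

#' Map a coefficient row back onto the brain grid
#'
#' The inverse of the flattening used by [load_fmri()]: `values[j]` is
#' placed at grid coordinate `voxel_index[j, ]`, all other cells are zero.
#'
#' @param values length-n numeric vector (one row of the coefficient matrix,
#'   or any per-voxel statistic).
#' @param mask the `brain_mask` defining the grid.
#' @param voxel_index n x 3 matrix of 0-based coordinates, as stored in a
#'   `signal_matrix`.
#' @return a 3D numeric array.
#' @export
map_row_to_volume <- function(values, mask, voxel_index) {
  if (!inherits(mask, "brain_mask")) abort_value("mask must be a brain_mask")
  voxel_index <- as.matrix(voxel_index)
  if (length(values) != nrow(voxel_index)) {
    abort_shape(sprintf("length(values) == %d but voxel_index has %d rows",
                        length(values), nrow(voxel_index)))
  }
  vol <- array(0, dim(mask$grid))
  vol[voxel_index + 1L] <- as.numeric(values)
  vol
}

#' Extract per-voxel values from a volume
#'
#' Companion to [map_row_to_volume()]: reads the grid cells listed in
#' `voxel_index`, in order. `flatten_volume(map_row_to_volume(v, ...), ...)`
#' returns `v` exactly.
#'
#' @inheritParams map_row_to_volume
#' @param vol 3D array.
#' @return numeric vector of length `nrow(voxel_index)`.
#' @export
flatten_volume <- function(vol, voxel_index) {
  voxel_index <- as.matrix(voxel_index)
  if (!all(dim(vol) > apply(voxel_index, 2, max))) {
    abort_shape("voxel_index exceeds volume dimensions")
  }
  vol[voxel_index + 1L]
}

#' Write a 3D or 4D volume as NIfTI
#'
#' Output maps inherit the mask's header geometry (affine, pixel
#' dimensions) when a reference image is available.
#'
#' @param vol numeric or logical array.
#' @param path output file (.nii or .nii.gz).
#' @param mask optional `brain_mask` supplying header geometry.
#' @param tr_seconds repetition time stamped into the 4th pixdim slot for
#'   4D output.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, mask = NULL, tr_seconds = NULL) {
  vol <- array(as.numeric(vol), dim(vol))
  img <- if (!is.null(mask) && !is.null(mask$reference)) {
    RNifti::asNifti(vol, reference = mask$reference)
  } else {
    RNifti::asNifti(vol)
  }
  if (length(dim(vol)) == 4L && !is.null(tr_seconds) && is.finite(tr_seconds)) {
    RNifti::pixdim(img) <- c(RNifti::pixdim(img)[1:3], tr_seconds)
  }
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
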