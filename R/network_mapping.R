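# From coefficient rows to candidate functional networks. Each row of
# the coefficient matrix is the spatial loading of one atom; mapped back
# to the grid, z-scored over in-mask voxels and thresholded two-sided it
# becomes a candidate network map. The threshold is two-sided because the
# sign of a learned atom (and hence of its whole coefficient row) is
# arbitrary.

new_network_component <- function(index, timecourse, raw_map, z_map,
                                  binary_map, n_active, empty = FALSE) {
  structure(
    list(index = index, timecourse = timecourse, raw_map = raw_map,
         z_map = z_map, binary_map = binary_map,
         n_active = n_active, empty = empty),
    class = "network_component"
  )
}

#' @export
print.network_component <- function(x, ...) {
  cat(sprintf("<network_component> atom %d, %d active voxels%s\n",
              x$index, x$n_active, if (x$empty) " (empty)" else ""))
  invisible(x)
}

#' Build candidate network components from a decomposition
#'
#' For each coefficient row: map onto the grid, z-score the mapped values
#' over all in-mask voxels (`z = (v - mean(v)) / sd(v)`; voxels removed
#' during normalization contribute their implicit zero loading), and
#' binarize at `|z| > z_thresh`. A row with zero variance carries no
#' spatial structure and yields an empty component (flagged, not an
#' error).
#'
#' @param D m x k dictionary; column j supplies component j's timecourse.
#' @param alpha k x n coefficient matrix.
#' @param mask `brain_mask` defining the grid.
#' @param voxel_index n x 3 voxel coordinates for the columns of `alpha`.
#' @param z_thresh two-sided z threshold (default 2.0).
#' @return a list of `network_component` objects, ordered by atom index.
#' @export
build_components <- function(D, alpha, mask, voxel_index, z_thresh = 2.0) {
  if (nrow(alpha) != ncol(D)) {
    abort_shape("alpha must have one row per dictionary atom")
  }
  if (ncol(alpha) != nrow(voxel_index)) {
    abort_shape("alpha columns must match voxel_index rows")
  }
  if (!is.numeric(z_thresh) || length(z_thresh) != 1L || z_thresh < 0) {
    abort_value("z_thresh must be a single non-negative number")
  }
  dims <- dim(mask$grid)
  in_mask <- which(mask$grid)
  lapply(seq_len(nrow(alpha)), function(i) {
    raw <- map_row_to_volume(alpha[i, ], mask, voxel_index)
    v <- raw[in_mask]
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      return(new_network_component(
        index = i, timecourse = D[, i], raw_map = raw,
        z_map = array(0, dims), binary_map = array(FALSE, dims),
        n_active = 0L, empty = TRUE))
    }
    z <- array(0, dims)
    z[in_mask] <- (v - mean(v)) / s
    act <- array(FALSE, dims)
    act[in_mask] <- abs(z[in_mask]) > z_thresh
    new_network_component(
      index = i, timecourse = D[, i], raw_map = raw,
      z_map = z, binary_map = act,
      n_active = sum(act), empty = FALSE)
  })
}

#' Summarize components in a table
#'
#' One row per component: atom index, active-voxel count, peak |z| and
#' the 0-based coordinate of the peak.
#'
#' @param components list of `network_component` objects.
#' @return a data.frame with columns `index`, `n_active`, `peak_z`,
#'   `peak_x`, `peak_y`, `peak_z_coord`.
#' @export
component_summary <- function(components) {
  if (length(components) == 0L) {
    return(data.frame(index = integer(0), n_active = integer(0),
                      peak_z = numeric(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z_coord = integer(0)))
  }
  rows <- lapply(components, function(cp) {
    if (cp$empty || all(cp$z_map == 0)) {
      data.frame(index = cp$index, n_active = cp$n_active, peak_z = NA_real_,
                 peak_x = NA_integer_, peak_y = NA_integer_,
                 peak_z_coord = NA_integer_)
    } else {
      w <- which.max(abs(cp$z_map))
      co <- arrayInd(w, dim(cp$z_map)) - 1L
      data.frame(index = cp$index, n_active = cp$n_active,
                 peak_z = abs(cp$z_map[w]),
                 peak_x = co[1], peak_y = co[2], peak_z_coord = co[3])
    }
  })
  do.call(rbind, rows)
}
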