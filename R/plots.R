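# PNG rendering of component and group maps. Views are axial: the
# "most informative slice" of a map is the axial slice with the largest
# in-slice sum of |values|.

#' Most informative axial slice of a 3D map
#'
#' @param vol 3D numeric array.
#' @return 1-based index along the third axis maximizing `sum(abs(slice))`.
#' @export
most_informative_slice <- function(vol) {
  which.max(apply(abs(vol), 3L, sum))
}

draw_slice <- function(slice, zlim, main = NULL) {
  image(t(slice), zlim = zlim, col = hcl.colors(64, "Blue-Red 3"),
        axes = FALSE, useRaster = TRUE)
  if (!is.null(main)) mtext(main, side = 3, line = 0.2, cex = 0.7)
}

#' Write an axial mosaic PNG of a z-map
#'
#' Renders every `by`-th axial slice on an anatomy-free background.
#'
#' @param z_map 3D numeric array of z values.
#' @param file output PNG path.
#' @param by slice stride.
#' @param title_text optional label drawn above the mosaic.
#' @return `file`, invisibly.
#' @export
component_png <- function(z_map, file, by = 2L, title_text = NULL) {
  nz <- dim(z_map)[3]
  slices <- seq(1L, nz, by = by)
  ncols <- ceiling(sqrt(length(slices)))
  nrows <- ceiling(length(slices) / ncols)
  zmax <- max(abs(z_map), 1e-6)
  png(file, width = 120 * ncols, height = 120 * nrows + 20)
  op <- par(mfrow = c(nrows, ncols), mar = c(0.2, 0.2, 1.0, 0.2), oma = c(0, 0, 1.2, 0))
  on.exit({ par(op); dev.off() }, add = TRUE)
  for (s in slices) draw_slice(z_map[, , s], zlim = c(-zmax, zmax))
  if (!is.null(title_text)) mtext(title_text, outer = TRUE, cex = 0.9)
  invisible(file)
}

#' Write a single-slice montage PNG for a matched group network
#'
#' Shows the most informative axial slice, coding template-only, map-only
#' and agreement voxels as distinct levels.
#'
#' @param group_map 3D logical group consensus map.
#' @param template 3D logical template map.
#' @param file output PNG path.
#' @param label label drawn on the image.
#' @return `file`, invisibly.
#' @export
montage_png <- function(group_map, template, file, label = NULL) {
  comb <- (template != 0) * 1 + (group_map != 0) * 2   # 0 bg, 1 tmpl, 2 map, 3 both
  s <- most_informative_slice(comb)
  png(file, width = 320, height = 340)
  op <- par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit({ par(op); dev.off() }, add = TRUE)
  image(t(comb[, , s]), zlim = c(0, 3),
        col = c("black", "navy", "darkred", "yellow"),
        axes = FALSE, useRaster = TRUE)
  if (!is.null(label)) title(main = label, cex.main = 0.9)
  invisible(file)
}
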