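#' Resample a binary mask to a new spacing
#'
#' The 0/1 indicator field is interpolated trilinearly at the voxel centers
#' of the output grid and thresholded at 0.5, with ties (exactly 0.5)
#' mapping to foreground. The output grid shares the input origin (the
#' first voxel centers coincide) and is the smallest grid whose centers
#' cover the physical extent of the input center lattice, so world-space
#' geometry is preserved.
#'
#' @param mask A [binary_mask()].
#' @param target_spacing Positive spacing in mm (scalar or triple).
#' @return A [binary_mask()] on the resampled grid.
#' @examples
#' g <- image_grid(c(6, 6, 6), spacing = 2)
#' v <- array(FALSE, g$shape); v[3:4, 3:4, 3:4] <- TRUE
#' fine <- resample_mask(binary_mask(v, g), 1)
#' fine$grid$spacing
#' @export
resample_mask <- function(mask, target_spacing) {
  ts <- as_spacing3(target_spacing, "target_spacing")
  g <- mask$grid
  extent <- (g$shape - 1) * g$spacing
  out_shape <- as.integer(ceiling(extent / ts - 1e-9)) + 1L
  vals <- cpp_trilinear(as.numeric(mask$values), g$shape, g$spacing,
                        out_shape, ts)
  fg <- array(vals >= 0.5 - 1e-12, out_shape)
  binary_mask(fg, image_grid(out_shape, ts, g$origin))
}

# Represent the foreground voxel CENTERS on the dense lattice: each source
# foreground center is snapped to its nearest dense voxel (exact when the
# spacing ratio is an integer; otherwise off by at most half a dense
# voxel). Used as the distance reference of the dense map, so sparse and
# dense maps measure distance to the same solid point set.
snap_centers <- function(mask, target_spacing) {
  ts <- as_spacing3(target_spacing, "target_spacing")
  g <- mask$grid
  extent <- (g$shape - 1) * g$spacing
  out_shape <- as.integer(ceiling(extent / ts - 1e-9)) + 1L
  idx <- foreground_indices(mask)
  didx <- sweep(
    round(sweep(idx - 1, 2, g$spacing / ts, "*")) + 1, 2, out_shape, pmin)
  didx[didx < 1] <- 1L
  v <- array(FALSE, out_shape)
  v[cbind(didx[, 1], didx[, 2], didx[, 3])] <- TRUE
  binary_mask(v, image_grid(out_shape, ts, g$origin))
}
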