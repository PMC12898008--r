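#' Safety-margin specification for dangerous-region generation
#'
#' Bundles the tunable parameters of the pipeline. `band_mm` is the
#' half-width of the refinement shell around the margin isosurface that is
#' re-decided at dense resolution; its default, half the source voxel
#' diagonal, is the maximal per-voxel decision uncertainty of the sparse
#' distance map. `pad_mm` defaults to `margin_mm + 20`, the ROI extension
#' beyond the safety margin.
#'
#' @param margin_mm Positive safety margin in mm (10/15/20 in clinical use).
#' @param band_mm Non-negative refinement half-width in mm, or `NULL` to
#'   derive it from the source spacing at generation time.
#' @param pad_mm ROI padding in mm; must be at least `margin_mm` so the
#'   region fits inside the crop.
#' @param dense_spacing Spacing (mm) of the dense grid, or `NULL` for half
#'   the minimum source spacing (isotropic).
#' @param restrict_to_bone If `TRUE`, intersect the region with the union of
#'   bone and tumor masks.
#' @return An object of class `margin_spec`.
#' @export
margin_spec <- function(margin_mm, band_mm = NULL, pad_mm = margin_mm + 20,
                        dense_spacing = NULL, restrict_to_bone = FALSE) {
  check_scalar_num(margin_mm, "margin_mm", lower = 0, allow_zero = TRUE)
  if (!is.null(band_mm)) check_scalar_num(band_mm, "band_mm", lower = 0)
  check_scalar_num(pad_mm, "pad_mm", lower = 0)
  if (pad_mm < margin_mm) stop("'pad_mm' must be >= 'margin_mm'")
  if (!is.null(dense_spacing)) dense_spacing <- as_spacing3(dense_spacing,
                                                           "dense_spacing")
  structure(list(margin_mm = margin_mm, band_mm = band_mm, pad_mm = pad_mm,
                 dense_spacing = dense_spacing,
                 restrict_to_bone = isTRUE(restrict_to_bone)),
            class = "margin_spec")
}

#' Coarse dangerous region by thresholding the sparse distance map
#'
#' Foreground wherever the distance to the tumor is at most `margin_mm`
#' (inclusive: a point exactly at the margin is dangerous), on the
#' original-resolution grid.
#'
#' @param sparse_map A `distance_map` from [distance_transform()].
#' @param margin_mm Non-negative margin in mm.
#' @return A [binary_mask()] on the sparse grid.
#' @export
coarse_region <- function(sparse_map, margin_mm) {
  check_scalar_num(margin_mm, "margin_mm", lower = 0)
  binary_mask(sparse_map$values <= margin_mm, sparse_map$grid)
}

#' Fine dangerous ring from the dense distance map
#'
#' The uncertainty shell of the coarse grid, re-decided at dense
#' resolution: dense-grid voxels whose distance lies in
#' `(margin_mm - band_mm, margin_mm]`.
#'
#' @param dense_map A `distance_map` on the dense grid.
#' @param margin_mm Margin in mm.
#' @param band_mm Shell half-width, `0 <= band_mm <= margin_mm`.
#' @return A [binary_mask()] on the dense grid.
#' @export
fine_ring <- function(dense_map, margin_mm, band_mm) {
  check_scalar_num(margin_mm, "margin_mm", lower = 0)
  check_scalar_num(band_mm, "band_mm", lower = 0)
  if (band_mm > margin_mm) stop("'band_mm' must not exceed 'margin_mm'")
  v <- dense_map$values
  binary_mask(v > margin_mm - band_mm & v <= margin_mm, dense_map$grid)
}

# nearest-world-position upsampling of a coarse array onto a dense grid
# sharing the same origin
upsample_nearest <- function(values, src_grid, dst_grid) {
  ix <- lapply(1:3, function(a) {
    pos <- (seq_len(dst_grid$shape[a]) - 1) * dst_grid$spacing[a] +
      (dst_grid$origin[a] - src_grid$origin[a])
    i <- as.integer(round(pos / src_grid$spacing[a])) + 1L
    pmin(pmax(i, 1L), src_grid$shape[a])
  })
  values[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

# foreground voxels with at least one background 6-neighbor (out-of-grid
# counts as background)
boundary_voxel_mask <- function(vals) {
  d <- dim(vals)
  if (any(d < 2L)) return(vals)  # slab: every foreground voxel is boundary
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  interior <- vals
  sh <- array(FALSE, d); sh[2:nx, , ] <- vals[1:(nx - 1), , ]
  interior <- interior & sh
  sh[] <- FALSE; sh[1:(nx - 1), , ] <- vals[2:nx, , ]
  interior <- interior & sh
  sh[] <- FALSE; sh[, 2:ny, ] <- vals[, 1:(ny - 1), ]
  interior <- interior & sh
  sh[] <- FALSE; sh[, 1:(ny - 1), ] <- vals[, 2:ny, ]
  interior <- interior & sh
  sh[] <- FALSE; sh[, , 2:nz] <- vals[, , 1:(nz - 1)]
  interior <- interior & sh
  sh[] <- FALSE; sh[, , 1:(nz - 1)] <- vals[, , 2:nz]
  interior <- interior & sh
  vals & !interior
}

#' Combine coarse-interior and fine-ring masks into a dangerous region
#'
#' The final dense mask is the union of the trusted coarse interior
#' (sparse distance at most `margin - band`, upsampled to the dense grid by
#' nearest world position) and the fine ring. Boundary points are the
#' centers of dense foreground voxels with at least one background
#' 6-neighbor.
#'
#' @param interior [binary_mask()] on the sparse grid: voxels with sparse
#'   distance `<= margin_mm - band_mm` (the part of the coarse region that
#'   the dense map does not re-decide).
#' @param ring [binary_mask()] on the dense grid from [fine_ring()].
#' @param spec A [margin_spec()] recorded as provenance.
#' @param clip Optional [binary_mask()] on the sparse grid (e.g. bone union
#'   tumor); when given, the dense mask is intersected with its
#'   nearest-neighbor upsampling.
#' @return A `dangerous_region`: `dense_mask`, `boundary_points` (world mm),
#'   and `provenance`.
#' @export
combine_regions <- function(interior, ring, spec, clip = NULL) {
  if (max(abs(interior$grid$origin - ring$grid$origin)) > 1e-6)
    stop("geometry error: coarse and dense grids have different origins")
  ext_c <- (interior$grid$shape - 1) * interior$grid$spacing
  ext_d <- (ring$grid$shape - 1) * ring$grid$spacing
  if (max(abs(ext_c - ext_d)) > max(interior$grid$spacing) + 1e-6)
    stop("geometry error: coarse and dense grids cover different extents")
  up <- upsample_nearest(interior$values, interior$grid, ring$grid)
  dense <- up | ring$values
  if (!is.null(clip)) {
    dense <- dense & upsample_nearest(clip$values, clip$grid, ring$grid)
  }
  dense_mask <- binary_mask(dense, ring$grid)
  bmask <- boundary_voxel_mask(dense)
  bpts <- voxel_to_world(ring$grid, which(bmask, arr.ind = TRUE))
  structure(list(dense_mask = dense_mask,
                 boundary_points = bpts,
                 provenance = spec),
            class = "dangerous_region")
}

#' Generate the patient-specific dangerous region
#'
#' Runs the full pipeline: crop the tumor ROI with `pad_mm` of physical
#' padding, resample the cropped tumor to the dense grid, apply the exact
#' anisotropic distance transform at both resolutions, threshold the sparse
#' map into a coarse region, re-decide the shell around the margin
#' isosurface on the dense map (fine ring), and take the union on the dense
#' grid. The result contains the tumor plus all surrounding tissue within
#' the safety margin. All stages are deterministic.
#'
#' @param tumor Nonempty [binary_mask()].
#' @param bone Optional [binary_mask()] on the same grid; required when
#'   `restrict_to_bone = TRUE`.
#' @param margin_mm Positive safety margin (mm).
#' @param band_mm Refinement half-width (mm); default half the source voxel
#'   diagonal, clamped to `margin_mm`.
#' @param pad_mm ROI padding (mm), default `margin_mm + 20`.
#' @param dense_spacing Dense-grid spacing (mm); default half the minimum
#'   source spacing, isotropic.
#' @param restrict_to_bone Intersect the region with bone-union-tumor.
#' @return A `dangerous_region` object.
#' @examples
#' ph <- make_phantom("sphere", radius = 6,
#'                    grid = image_grid(c(40, 40, 40), 1))
#' reg <- generate_dangerous_region(ph$tumor, margin_mm = 5)
#' summary(reg)
#' @export
generate_dangerous_region <- function(tumor, bone = NULL, margin_mm,
                                      band_mm = NULL,
                                      pad_mm = margin_mm + 20,
                                      dense_spacing = NULL,
                                      restrict_to_bone = FALSE) {
  if (!any(tumor$values)) stop(empty_foreground_error())
  if (!is.null(bone) && !all(bone$grid$shape == tumor$grid$shape))
    stop("geometry error: tumor and bone must share a grid")
  if (restrict_to_bone && is.null(bone))
    stop("restrict_to_bone = TRUE requires a bone mask")
  g <- tumor$grid
  if (is.null(band_mm)) band_mm <- 0.5 * sqrt(sum(g$spacing^2))
  band_mm <- min(band_mm, margin_mm)
  if (is.null(dense_spacing)) dense_spacing <- rep(min(g$spacing) / 2, 3)
  spec <- margin_spec(margin_mm, band_mm, pad_mm, dense_spacing,
                      restrict_to_bone)

  cr <- crop_roi(tumor, pad_mm)
  tumor_crop <- cr$mask
  # the crop must leave room for the full margin around the tumor
  fg <- foreground_indices(tumor_crop)
  if (any(fg == 1L) ||
      any(sweep(fg, 2, tumor_crop$grid$shape, "==")))
    stop(structure(class = c("osteomargin_pad_too_small", "error", "condition"),
                   list(message = "pad-too-small: tumor touches the crop boundary after padding",
                        call = sys.call(-1))))

  sparse_map <- distance_transform(tumor_crop)
  # Reference set of the dense map: the tumor voxel centers snapped onto
  # the dense lattice, so sparse and dense maps measure distance to the
  # same solid and the dense decision errs by at most half a dense voxel
  # diagonal (a thresholded trilinear resample would bias the dense map by
  # up to half a SOURCE voxel in concave corners).
  tumor_dense <- snap_centers(tumor_crop, dense_spacing)
  dense_map <- distance_transform(tumor_dense)

  interior <- binary_mask(sparse_map$values <= margin_mm - band_mm,
                          sparse_map$grid)
  # Re-decide, at dense resolution, exactly the voxels whose coarse
  # decision is uncertain (nearest sparse distance within one band of the
  # margin); thresholding both ring bounds on the dense map instead would
  # leave holes where the dense distance is already below margin - band
  # but the nearest coarse voxel sits just outside the trusted interior.
  sparse_up <- upsample_nearest(sparse_map$values, sparse_map$grid,
                                dense_map$grid)
  ring <- binary_mask(dense_map$values <= margin_mm &
                        sparse_up > margin_mm - band_mm,
                      dense_map$grid)

  clip <- NULL
  if (restrict_to_bone) {
    bone_crop <- binary_mask(
      bone$values[cr$box$lo[1]:cr$box$hi[1], cr$box$lo[2]:cr$box$hi[2],
                  cr$box$lo[3]:cr$box$hi[3], drop = FALSE],
      tumor_crop$grid)
    clip <- binary_mask(bone_crop$values | tumor_crop$values, tumor_crop$grid)
  }
  region <- combine_regions(interior, ring, spec, clip = clip)
  region$provenance$source_spacing <- g$spacing
  region$provenance$crop_box <- cr$box
  region
}

#' @export
print.dangerous_region <- function(x, ...) {
  m <- x$dense_mask
  cat(sprintf("<dangerous_region> margin %g mm, band %g mm\n",
              x$provenance$margin_mm, x$provenance$band_mm))
  cat(sprintf("  dense grid: %d x %d x %d @ (%g, %g, %g) mm\n",
              m$grid$shape[1], m$grid$shape[2], m$grid$shape[3],
              m$grid$spacing[1], m$grid$spacing[2], m$grid$spacing[3]))
  cat(sprintf("  volume %.1f mm^3, %d boundary points\n",
              mask_volume(m), nrow(x$boundary_points)))
  invisible(x)
}

#' @export
summary.dangerous_region <- function(object, ...) {
  out <- list(margin_mm = object$provenance$margin_mm,
              band_mm = object$provenance$band_mm,
              dense_spacing = object$dense_mask$grid$spacing,
              voxel_count = sum(object$dense_mask$values),
              volume_mm3 = mask_volume(object$dense_mask),
              n_boundary_points = nrow(object$boundary_points))
  class(out) <- "summary.dangerous_region"
  out
}

#' @export
print.summary.dangerous_region <- function(x, ...) {
  cat(sprintf("Dangerous region: margin %g mm (band %g mm)\n",
              x$margin_mm, x$band_mm))
  cat(sprintf("  dense spacing (%g, %g, %g) mm\n", x$dense_spacing[1],
              x$dense_spacing[2], x$dense_spacing[3]))
  cat(sprintf("  %d voxels, %.1f mm^3, %d boundary points\n",
              x$voxel_count, x$volume_mm3, x$n_boundary_points))
  invisible(x)
}

#' @export
plot.dangerous_region <- function(x, ...) {
  v <- x$dense_mask$values
  d <- dim(v)
  op <- par(mfrow = c(1, 3), mar = c(2, 2, 2, 1))
  on.exit(par(op))
  sl <- list(v[ceiling(d[1] / 2), , ], v[, ceiling(d[2] / 2), ],
             v[, , ceiling(d[3] / 2)])
  lab <- c("sagittal", "coronal", "axial")
  for (i in 1:3) {
    image(sl[[i]] * 1, col = gray.colors(2, start = 0, end = 1),
          axes = FALSE, useRaster = TRUE)
    title(lab[i])
  }
  invisible(x)
}

#' Brute-force margin region (test oracle)
#'
#' Marks every voxel of `target_grid` whose center lies within `margin_mm`
#' (world metric) of some tumor foreground voxel center, by direct
#' minimization over all pairs -- no transform, no resampling. Quadratic
#' cost; intended for grids up to roughly 32^3.
#'
#' @param tumor Nonempty [binary_mask()].
#' @param margin_mm Non-negative margin (mm).
#' @param target_grid The [image_grid()] to rasterize onto (default: the
#'   tumor's own grid).
#' @return A [binary_mask()] on `target_grid`.
#' @export
oracle_region <- function(tumor, margin_mm, target_grid = tumor$grid) {
  if (!any(tumor$values)) stop(empty_foreground_error())
  check_scalar_num(margin_mm, "margin_mm", lower = 0)
  tp <- foreground_world(tumor)
  ax <- axis_coords(target_grid)
  cen <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  d2 <- rep(Inf, nrow(cen))
  cn <- rowSums(cen^2)
  step <- 128L
  for (s in seq(1, nrow(tp), by = step)) {
    e <- min(s + step - 1L, nrow(tp))
    blk <- tp[s:e, , drop = FALSE]
    # squared distances from every center to this block of tumor points
    m <- outer(cn, rowSums(blk^2), "+") - 2 * (cen %*% t(blk))
    d2 <- pmin(d2, do.call(pmin, as.data.frame(m)))
  }
  binary_mask(array(sqrt(pmax(d2, 0)) <= margin_mm, target_grid$shape),
              target_grid)
}
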