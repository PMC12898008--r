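#' Crop a region of interest around the mask foreground
#'
#' Tight foreground bounding box, extended by `ceiling(pad_mm / spacing)`
#' voxels per side on each axis and clipped to the grid. For the
#' dangerous-region pipeline the pad is the safety margin plus 20 mm, so the
#' distance transform has room beyond the margin isosurface.
#'
#' @param mask A [binary_mask()] with at least one foreground voxel.
#' @param pad_mm Non-negative physical padding in mm.
#' @return A list with elements `mask` (the cropped [binary_mask()], origin
#'   shifted accordingly) and `box` (a `bounding_box`: 1-based inclusive
#'   `lo`/`hi` indices into the parent grid).
#' @examples
#' g <- image_grid(c(11, 11, 11))
#' v <- array(FALSE, g$shape); v[6, 6, 6] <- TRUE
#' crop_roi(binary_mask(v, g), pad_mm = 0)$box$lo
#' @export
crop_roi <- function(mask, pad_mm) {
  check_scalar_num(pad_mm, "pad_mm", lower = 0)
  if (!any(mask$values))
    stop(empty_foreground_error())
  g <- mask$grid
  rng <- lapply(1:3, function(a) {
    any_fg <- apply(mask$values, a, any)
    range(which(any_fg))
  })
  lo <- vapply(rng, `[`, integer(1), 1L)
  hi <- vapply(rng, `[`, integer(1), 2L)
  padv <- as.integer(ceiling(pad_mm / g$spacing - 1e-9))
  lo <- pmax(1L, lo - padv)
  hi <- pmin(g$shape, hi + padv)
  sub <- mask$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  newgrid <- image_grid(hi - lo + 1L, g$spacing,
                        g$origin + (lo - 1) * g$spacing)
  box <- structure(list(lo = lo, hi = hi, grid = g), class = "bounding_box")
  list(mask = binary_mask(sub, newgrid), box = box)
}

#' Paste a cropped mask back into its parent grid
#'
#' Inverse of [crop_roi()]: voxels outside the box are background.
#'
#' @param submask The cropped [binary_mask()].
#' @param box The `bounding_box` returned by [crop_roi()].
#' @return A [binary_mask()] on the parent grid.
#' @export
uncrop <- function(submask, box) {
  g <- box$grid
  if (!all(dim(submask$values) == box$hi - box$lo + 1L))
    stop("submask extent does not match bounding box")
  v <- array(FALSE, g$shape)
  v[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <-
    submask$values
  binary_mask(v, g)
}

empty_foreground_error <- function() {
  structure(class = c("osteomargin_empty_foreground", "error", "condition"),
            list(message = "empty-foreground: mask has no foreground voxels",
                 call = sys.call(-1)))
}
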