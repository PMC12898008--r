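#' Voxel lattice with physical spacing
#'
#' An `image_grid` describes a 3D voxel lattice: integer extent `shape`,
#' per-axis physical spacing in millimetres, and the world position (mm) of
#' the center of voxel `(1, 1, 1)`. The world coordinate of voxel
#' `(i, j, k)` is `origin + ((i, j, k) - 1) * spacing`. Axes are assumed
#' world-aligned (no rotation); this matches axis-aligned CT exports.
#'
#' @param shape Integer triple `(nx, ny, nz)`.
#' @param spacing Positive spacing in mm; a scalar is recycled to 3.
#' @param origin World position (mm) of the center of the first voxel.
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(64, 64, 32), spacing = c(0.8, 0.8, 3))
#' voxel_to_world(g, cbind(1, 1, 1))
#' @export
image_grid <- function(shape, spacing = 1, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L))
    stop("'shape' must be three positive integers")
  spacing <- as_spacing3(spacing)
  origin <- as.numeric(origin)
  if (length(origin) != 3L || anyNA(origin))
    stop("'origin' must be a numeric triple")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Convert voxel indices to world coordinates
#'
#' @param grid An [image_grid()].
#' @param idx Integer matrix (n x 3) of 1-based voxel indices.
#' @return Numeric matrix (n x 3) of world positions in mm.
#' @export
voxel_to_world <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' Convert world coordinates to (fractional) voxel indices
#'
#' @inheritParams voxel_to_world
#' @param xyz Numeric matrix (n x 3) of world positions in mm.
#' @return Numeric matrix of fractional 1-based indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
}

#' Binary voxel mask on a physical grid
#'
#' @param values Logical (or 0/1) array matching `grid$shape`.
#' @param grid An [image_grid()].
#' @return An object of class `binary_mask`.
#' @examples
#' g <- image_grid(c(8, 8, 8))
#' v <- array(FALSE, g$shape); v[4, 4, 4] <- TRUE
#' m <- binary_mask(v, g)
#' mask_volume(m)
#' @export
binary_mask <- function(values, grid) {
  if (!inherits(grid, "image_grid")) stop("'grid' must be an image_grid")
  if (is.numeric(values) || is.integer(values)) values <- values != 0
  if (!is.logical(values)) stop("'values' must be logical or 0/1")
  dv <- dim(values)
  if (is.null(dv) || length(dv) != 3L || !all(dv == grid$shape))
    stop("dim(values) must equal grid$shape")
  if (anyNA(values)) stop("'values' must not contain NA")
  structure(list(values = values, grid = grid), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  n <- sum(x$values)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d foreground (%.1f mm^3)\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              n, n * prod(x$grid$spacing)))
  invisible(x)
}

#' Foreground volume of a mask in cubic millimetres
#' @param mask A [binary_mask()].
#' @return Foreground voxel count times the voxel volume (mm^3).
#' @export
mask_volume <- function(mask) {
  sum(mask$values) * prod(mask$grid$spacing)
}

#' Foreground voxel indices of a mask
#' @param mask A [binary_mask()].
#' @return Integer matrix (n x 3) of 1-based indices.
#' @export
foreground_indices <- function(mask) {
  which(mask$values, arr.ind = TRUE)
}

#' World coordinates (mm) of foreground voxel centers
#' @param mask A [binary_mask()].
#' @return Numeric matrix (n x 3).
#' @export
foreground_world <- function(mask) {
  voxel_to_world(mask$grid, foreground_indices(mask))
}

# world coordinates of every voxel center, as three per-axis vectors
axis_coords <- function(grid) {
  lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
}

#' Read a binary mask from a NIfTI file
#'
#' Spacing is taken from the header `pixdim`; the origin is the translation
#' part of the stored transform. Only axis-aligned transforms are supported:
#' masks are kept in the header's own frame, no axes are flipped.
#'
#' @param path Path to a `.nii` or `.nii.gz` file storing 0/1 values.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop(structure(class = c("osteomargin_missing_file", "error", "condition"),
                   list(message = sprintf("file not found: %s", path),
                        call = sys.call(-1))))
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L) stop("expected a 3D NIfTI volume")
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3] - diag(sp)
  if (max(abs(rot)) > 1e-4 * max(sp))
    warning("non-axis-aligned NIfTI transform; using pixdim spacing and translation only")
  origin <- xf[1:3, 4]
  binary_mask(array(as.array(img) != 0, dm),
              image_grid(dm, sp, origin))
}

#' Write a binary mask to a NIfTI file
#'
#' Values are stored as 8-bit 0/1; spacing goes into `pixdim` and the origin
#' into the qform/sform translation.
#'
#' @param mask A [binary_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  a <- array(as.integer(mask$values), mask$grid$shape)
  attr(a, "pixdim") <- mask$grid$spacing
  img <- RNifti::asNifti(a)
  m <- diag(c(mask$grid$spacing, 1))
  m[1:3, 4] <- mask$grid$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
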