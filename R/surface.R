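#' Reconstruct a closed triangulated surface from a point cloud
#'
#' Builds a watertight triangle mesh enclosing the input points. At
#' `shrink = 0` the result is the convex hull. For `shrink > 0` the point
#' set is Delaunay-tetrahedralized and boundary tetrahedra whose
#' circumradius exceeds an adaptive threshold are peeled away
#' (alpha-shape-style sculpting); `shrink = 1` peels down to a threshold of
#' twice the median nearest-neighbour spacing. Peeling preserves a
#' topological ball: the boundary stays a single watertight 2-manifold and
#' no input point is ever lost (every point remains a mesh vertex or strictly
#' inside the mesh). Duplicate points are removed first; collinear or
#' coplanar inputs are rejected, never perturbed into validity.
#'
#' @param points Numeric matrix (n x 3) of world positions (mm); at least 4
#'   non-coplanar points after deduplication.
#' @param shrink Tightening parameter in `[0, 1]`; 0 = convex hull, 1 =
#'   tightest enclosing surface. Default 1, the setting used for clinical
#'   region surfaces.
#' @return A `triangulated_surface`: `vertices` (m x 3 mm), `faces` (F x 3
#'   vertex indices, consistently wound with outward normals), `shrink`, and
#'   the supporting tetrahedral complex used for volume and containment
#'   queries.
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' s <- reconstruct_surface(cube, shrink = 0)
#' nrow(s$vertices); nrow(s$faces)  # 8 and 12
#' @export
reconstruct_surface <- function(points, shrink = 1) {
  points <- matrix(as.numeric(as.matrix(points)), ncol = 3)
  if (anyNA(points)) stop("'points' must not contain NA")
  if (length(shrink) != 1L || is.na(shrink) || shrink < 0 || shrink > 1)
    stop("'shrink' must be a single number in [0, 1]")
  points <- unique(points)
  if (nrow(points) < 4L)
    stop("degenerate-geometry: need at least 4 distinct points")
  res <- cpp_alpha_complex(points, shrink)
  faces_all <- res$faces
  tets <- res$tets
  alpha <- res$alpha
  used <- sort(unique(as.integer(faces_all)))
  remap <- integer(nrow(points))
  remap[used] <- seq_along(used)
  faces <- matrix(remap[faces_all], ncol = 3)
  structure(list(vertices = points[used, , drop = FALSE],
                 faces = faces,
                 shrink = shrink,
                 alpha = alpha,
                 points = points,
                 point_vertex = used,
                 tets = tets),
            class = "triangulated_surface")
}

#' @export
print.triangulated_surface <- function(x, ...) {
  cat(sprintf("<triangulated_surface> %d vertices, %d faces, shrink %g\n",
              nrow(x$vertices), nrow(x$faces), x$shrink))
  cat(sprintf("  area %.2f mm^2, volume %.2f mm^3, watertight: %s\n",
              surface_area(x), mesh_volume(x), is_watertight(x)))
  invisible(x)
}

#' Total area of a triangulated surface (mm^2)
#' @param surface A `triangulated_surface`.
#' @return Sum of triangle areas.
#' @export
surface_area <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sum(sqrt(cx^2 + cy^2 + cz^2))
}

#' Enclosed volume of a closed surface (mm^3)
#'
#' Divergence-theorem sum of signed tetrahedra against the origin; positive
#' for a watertight, consistently outward-wound mesh.
#'
#' @param surface A `triangulated_surface`.
#' @return Enclosed volume.
#' @export
mesh_volume <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  s <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
    a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
    a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  sum(s) / 6
}

#' Check that every edge borders exactly two faces
#'
#' Watertightness test: the mesh is a closed 2-manifold iff each undirected
#' edge is shared by exactly two faces and each directed edge appears once
#' (consistent winding).
#'
#' @param surface A `triangulated_surface`.
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(surface) {
  f <- surface$faces
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  und <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  dir <- paste(ed[, 1], ed[, 2])
  all(table(und) == 2L) && !anyDuplicated(dir)
}

#' Reconstruct the dangerous-region surface
#'
#' Convenience wrapper: triangulates the region's boundary points.
#'
#' @param region A `dangerous_region`.
#' @param shrink Tightening parameter, see [reconstruct_surface()].
#' @return A `triangulated_surface`.
#' @export
region_surface <- function(region, shrink = 1) {
  reconstruct_surface(region$boundary_points, shrink = shrink)
}

#' Osteotomy plane
#'
#' A planned planar bone cut given as a point on the plane and a unit
#' normal; the positive-normal half-space is the safe side (away from the
#' tumor).
#'
#' @param point World position (mm) on the plane.
#' @param normal Plane normal (need not be unit length; normalized here).
#' @param name Optional label.
#' @return An object of class `osteotomy_plane`.
#' @export
osteotomy_plane <- function(point, normal, name = "") {
  point <- as.numeric(point)
  normal <- as.numeric(normal)
  if (length(point) != 3L || length(normal) != 3L || anyNA(c(point, normal)))
    stop("'point' and 'normal' must be numeric triples")
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("'normal' must be nonzero")
  structure(list(point = point, normal = normal / nn, name = name),
            class = "osteotomy_plane")
}

#' @export
print.osteotomy_plane <- function(x, ...) {
  cat(sprintf("<osteotomy_plane>%s point (%g, %g, %g), normal (%g, %g, %g)\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Read osteotomy planes from a JSON plan file
#'
#' The plan is a JSON list of objects `{point: [x,y,z], normal: [nx,ny,nz],
#' name}` in world mm.
#'
#' @param path Path to the JSON file.
#' @return List of [osteotomy_plane()] objects.
#' @export
read_plane_plan <- function(path) {
  if (!file.exists(path))
    stop(structure(class = c("osteomargin_missing_file", "error", "condition"),
                   list(message = sprintf("file not found: %s", path),
                        call = sys.call(-1))))
  pl <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(pl, function(p)
    osteotomy_plane(p$point, p$normal, if (is.null(p$name)) "" else p$name))
}

#' Signed clearance of an osteotomy plane from the dangerous region
#'
#' The plane's normal points away from the tumor, into the half-space that
#' must stay free of dangerous tissue. Positive clearance: the whole region
#' (boundary points and interior voxel centers) stays behind the plane by
#' that many mm. Negative: the region crosses the plane by that depth. The
#' plane is classified "safe" iff the clearance is non-negative.
#'
#' @param region A `dangerous_region`.
#' @param plane An [osteotomy_plane()].
#' @return Clearance in mm, with attribute `safe` (logical).
#' @examples
#' ph <- make_phantom("sphere", radius = 5, grid = image_grid(c(30, 30, 30), 1))
#' reg <- generate_dangerous_region(ph$tumor, margin_mm = 4)
#' pl <- osteotomy_plane(point = c(25, 14.5, 14.5), normal = c(1, 0, 0))
#' plane_clearance(reg, pl)
#' @export
plane_clearance <- function(region, plane) {
  m <- region$dense_mask
  if (!any(m$values)) stop(empty_foreground_error())
  g <- m$grid
  idx <- which(m$values) - 1L
  nx <- g$shape[1]; ny <- g$shape[2]
  i <- idx %% nx
  j <- (idx %/% nx) %% ny
  k <- idx %/% (nx * ny)
  # how far each foreground voxel center stays behind the plane
  d <- (plane$point[1] - g$origin[1] - i * g$spacing[1]) * plane$normal[1] +
    (plane$point[2] - g$origin[2] - j * g$spacing[2]) * plane$normal[2] +
    (plane$point[3] - g$origin[3] - k * g$spacing[3]) * plane$normal[3]
  cl <- min(d)
  attr(cl, "safe") <- cl >= 0
  cl
}

#' Write a surface as STL (binary) or PLY (ascii)
#'
#' Units are mm in a right-handed world frame with outward-facing normals.
#'
#' @param surface A `triangulated_surface`.
#' @param path Output path; format chosen by extension (`.stl` or `.ply`).
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") write_stl_binary(surface, path)
  else if (ext == "ply") write_ply_mesh(surface, path)
  else stop("unsupported surface format: use .stl or .ply")
  invisible(path)
}

write_stl_binary <- function(surface, path) {
  v <- surface$vertices
  f <- surface$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    n <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
           (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
           (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    nl <- sqrt(sum(n^2))
    if (nl > 0) n <- n / nl
    writeBin(as.numeric(c(n, a, b, cc)), con, size = 4, endian = "little")
    writeBin(as.integer(0L), con, size = 2, endian = "little")
  }
}

write_ply_mesh <- function(surface, path) {
  v <- surface$vertices
  f <- surface$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6g %.6g %.6g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

#' Write a point cloud as ascii PLY
#'
#' @param points Numeric matrix (n x 3), e.g. a region's `boundary_points`.
#' @param path Output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(points, path) {
  points <- matrix(as.numeric(as.matrix(points)), ncol = 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(points)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  writeLines(sprintf("%.6g %.6g %.6g", points[, 1], points[, 2], points[, 3]),
             con)
  invisible(path)
}

#' Test whether points lie inside or on a reconstructed surface
#'
#' Uses the supporting tetrahedral complex (or, for a convex hull, the face
#' half-spaces) with a small tolerance.
#'
#' @param surface A `triangulated_surface`.
#' @param pts Numeric matrix (n x 3).
#' @param tol Tolerance in mm (default 1e-6).
#' @return Logical vector.
#' @export
surface_contains <- function(surface, pts, tol = 1e-6) {
  pts <- matrix(as.numeric(as.matrix(pts)), ncol = 3)
  if (is.null(surface$tets)) {
    # convex hull: inside iff below every face plane
    v <- surface$vertices
    f <- surface$faces
    ok <- rep(TRUE, nrow(pts))
    for (i in seq_len(nrow(f))) {
      a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
      n <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
             (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
             (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
      nl <- sqrt(sum(n^2))
      if (nl == 0) next
      n <- n / nl
      ok <- ok & (sweep(pts, 2, a, "-") %*% n <= tol)
    }
    return(as.vector(ok))
  }
  # tet complex: inside iff contained in some tetrahedron
  P <- surface$points
  inside <- rep(FALSE, nrow(pts))
  tets <- surface$tets
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  faceopp <- rbind(c(2, 3, 4, 1), c(1, 3, 4, 2), c(1, 2, 4, 3), c(1, 2, 3, 4))
  for (t in seq_len(nrow(tets))) {
    rem <- which(!inside)
    if (!length(rem)) break
    vv <- P[tets[t, ], , drop = FALSE]
    q <- pts[rem, , drop = FALSE]
    ok <- rep(TRUE, nrow(q))
    for (f in 1:4) {
      a <- vv[faceopp[f, 1], ]
      n <- cross3(vv[faceopp[f, 2], ] - a, vv[faceopp[f, 3], ] - a)
      nl <- sqrt(sum(n^2))
      if (nl < 1e-300) { ok[] <- FALSE; break }
      n <- n / nl
      sop <- sum((vv[faceopp[f, 4], ] - a) * n)  # opposite-vertex side
      sq <- (q[, 1] - a[1]) * n[1] + (q[, 2] - a[2]) * n[2] +
        (q[, 3] - a[3]) * n[3]
      ok <- ok & (sq * sign(sop) >= -tol)
      if (!any(ok)) break
    }
    inside[rem[ok]] <- TRUE
  }
  inside
}
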