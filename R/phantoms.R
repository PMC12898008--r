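#' Synthetic tumor/bone phantoms with analytic ground truth
#'
#' Voxelizes simple solids by a voxel-center inclusion test (no
#' partial-volume fractions), so brute-force oracles over voxel centers are
#' exact. Available kinds:
#' \describe{
#'   \item{sphere}{ball of given `radius` (mm) at `center`}
#'   \item{ellipsoid}{axis-aligned semi-axes `radii = c(a, b, c)`}
#'   \item{two_lobe}{union of two spheres (`centers` 2 x 3, `radii` length 2)}
#'   \item{blob}{seeded union of 3--7 random axis-aligned ellipsoids}
#' }
#' The optional bone is a spherical shell sector around `center`:
#' inner/outer radius and a polar angular extent, minus the tumor. The
#' `truth` element carries closed-form volumes and, for sphere and
#' ellipsoid, the exact margin-dilated volume (Steiner formula; elliptic
#' coefficients by high-order quadrature for the ellipsoid).
#'
#' @param kind One of `"sphere"`, `"ellipsoid"`, `"two_lobe"`, `"blob"`.
#' @param grid An [image_grid()]; anisotropic spacing supported.
#' @param center Solid center in world mm (default: grid center).
#' @param radius Sphere radius (mm).
#' @param radii Ellipsoid semi-axes, or the two sphere radii for `two_lobe`.
#' @param centers 2 x 3 matrix of lobe centers for `two_lobe`.
#' @param bone `NULL` or `list(r_inner, r_outer, theta_max)` (mm, mm,
#'   radians) for the shell sector.
#' @param seed Integer seed, required for `kind = "blob"`; identical
#'   spec + seed gives bitwise-identical masks.
#' @return `list(tumor, bone, truth)`: two [binary_mask()]s (bone empty if
#'   not requested) and the analytic descriptors.
#' @examples
#' ph <- make_phantom("sphere", radius = 8, grid = image_grid(c(24, 24, 24), 1))
#' ph$truth$volume            # (4/3) pi 8^3
#' mask_volume(ph$tumor)      # close to it
#' @export
make_phantom <- function(kind = c("sphere", "ellipsoid", "two_lobe", "blob"),
                         grid, center = NULL, radius = NULL, radii = NULL,
                         centers = NULL, bone = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (!inherits(grid, "image_grid")) stop("'grid' must be an image_grid")
  extent <- (grid$shape - 1) * grid$spacing
  if (is.null(center)) center <- grid$origin + extent / 2
  center <- as.numeric(center)

  ax <- axis_coords(grid)
  insolid <- switch(kind,
    sphere = {
      check_scalar_num(radius, "radius", lower = 0, allow_zero = FALSE)
      solid_quadric(ax, center, rep(radius, 3))
    },
    ellipsoid = {
      radii <- as_spacing3(radii, "radii")
      solid_quadric(ax, center, radii)
    },
    two_lobe = {
      if (is.null(centers) || is.null(radii))
        stop("two_lobe needs 'centers' (2 x 3) and 'radii' (length 2)")
      centers <- matrix(as.numeric(centers), ncol = 3)
      solid_quadric(ax, centers[1, ], rep(radii[1], 3)) |
        solid_quadric(ax, centers[2, ], rep(radii[2], 3))
    },
    blob = {
      if (is.null(seed)) stop("blob phantom requires a 'seed'")
      if (is.null(radius)) radius <- min(extent) / 6
      lobes <- blob_lobes(seed, center, radius)
      v <- array(FALSE, grid$shape)
      for (lb in lobes) v <- v | solid_quadric(ax, lb$center, lb$radii)
      v
    })

  if (!any(insolid)) stop("tumor solid does not intersect the grid")
  # the tumor must sit strictly inside the grid
  fg <- which(insolid, arr.ind = TRUE)
  if (any(fg == 1L) || any(sweep(fg, 2, grid$shape, "==")))
    stop("tumor reaches the grid boundary; enlarge the grid")

  bone_vals <- array(FALSE, grid$shape)
  if (!is.null(bone)) {
    r2 <- radial2(ax, center)
    r <- sqrt(r2)
    z <- rep(ax[[3]] - center[3], each = grid$shape[1] * grid$shape[2])
    theta <- acos(pmin(pmax(ifelse(r > 0, z / r, 1), -1), 1))
    shell <- r >= bone$r_inner & r <= bone$r_outer &
      theta <= bone$theta_max
    bone_vals <- array(shell, grid$shape) & !insolid
  }

  truth <- phantom_truth(kind, radius, radii, centers, bone)
  list(tumor = binary_mask(insolid, grid),
       bone = binary_mask(bone_vals, grid),
       truth = truth)
}

# voxel-center inclusion for an axis-aligned ellipsoid
solid_quadric <- function(ax, center, radii) {
  qx <- ((ax[[1]] - center[1]) / radii[1])^2
  qy <- ((ax[[2]] - center[2]) / radii[2])^2
  qz <- ((ax[[3]] - center[3]) / radii[3])^2
  outer(outer(qx, qy, "+"), qz, "+") <= 1
}

radial2 <- function(ax, center) {
  qx <- (ax[[1]] - center[1])^2
  qy <- (ax[[2]] - center[2])^2
  qz <- (ax[[3]] - center[3])^2
  outer(outer(qx, qy, "+"), qz, "+")
}

# deterministic lobe parameters for the blob phantom
blob_lobes <- function(seed, center, radius) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  k <- sample(3:7, 1)
  lapply(seq_len(k), function(i) {
    list(center = center + runif(3, -radius / 2, radius / 2),
         radii = runif(3, radius / 3, radius))
  })
}

phantom_truth <- function(kind, radius, radii, centers, bone) {
  truth <- list(kind = kind)
  if (kind == "sphere") {
    truth$volume <- 4 / 3 * pi * radius^3
    truth$dilated_volume <- function(margin_mm)
      4 / 3 * pi * (radius + margin_mm)^3
  } else if (kind == "ellipsoid") {
    truth$volume <- 4 / 3 * pi * prod(radii)
    co <- ellipsoid_steiner(radii)
    truth$surface_area <- co$area
    truth$dilated_volume <- function(margin_mm)
      truth$volume + co$area * margin_mm + co$mean_curv_integral * margin_mm^2 +
        4 / 3 * pi * margin_mm^3
  } else if (kind == "two_lobe") {
    truth$lobe_volumes <- 4 / 3 * pi * radii^3
  }
  if (!is.null(bone))
    truth$bone_sector_volume <-
      2 / 3 * pi * (1 - cos(bone$theta_max)) * (bone$r_outer^3 - bone$r_inner^3)
  truth
}

# Steiner coefficients of an axis-aligned ellipsoid: surface area and the
# integral of mean curvature, by Gauss-Legendre product quadrature over the
# standard spherical parameterization. For equal semi-axes these reduce to
# 4 pi r^2 and 4 pi r.
ellipsoid_steiner <- function(radii, n = 96) {
  a <- radii[1]; b <- radii[2]; c3 <- radii[3]
  gl <- gauss_legendre(n)
  th <- pi / 2 * (gl$x + 1)           # theta in (0, pi), via symmetry use full
  wt <- gl$w * pi / 2
  ph <- pi * (gl$x + 1)               # phi in (0, 2 pi)
  wp <- gl$w * pi
  area <- 0; mint <- 0
  for (i in seq_len(n)) {
    st <- sin(th[i]); ct <- cos(th[i])
    for (j in seq_len(n)) {
      sp <- sin(ph[j]); cp <- cos(ph[j])
      # first fundamental form from r(theta, phi)
      rt <- c(a * ct * cp, b * ct * sp, -c3 * st)
      rp <- c(-a * st * sp, b * st * cp, 0)
      nvec <- c(rt[2] * rp[3] - rt[3] * rp[2],
                rt[3] * rp[1] - rt[1] * rp[3],
                rt[1] * rp[2] - rt[2] * rp[1])
      J <- sqrt(sum(nvec^2))
      if (J < 1e-300) next
      nunit <- nvec / J
      # second fundamental form
      rtt <- c(-a * st * cp, -b * st * sp, -c3 * ct)
      rtp <- c(-a * ct * sp, b * ct * cp, 0)
      rpp <- c(-a * st * cp, -b * st * sp, 0)
      E <- sum(rt^2); F2 <- sum(rt * rp); G <- sum(rp^2)
      L <- sum(rtt * nunit); M <- sum(rtp * nunit); N <- sum(rpp * nunit)
      H <- (E * N - 2 * F2 * M + G * L) / (2 * (E * G - F2^2))
      area <- area + wt[i] * wp[j] * J
      mint <- mint + wt[i] * wp[j] * abs(H) * J
    }
  }
  list(area = area, mean_curv_integral = mint)
}

# nodes/weights on (-1, 1) by Newton iteration on Legendre polynomials
gauss_legendre <- function(n) {
  x <- cos(pi * (seq_len(n) - 0.25) / (n + 0.5))
  for (it in 1:100) {
    p0 <- rep(1, n); p1 <- x
    for (k in 2:n) {
      p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
      p0 <- p1; p1 <- p2
    }
    dp <- n * (x * p1 - p0) / (x^2 - 1)
    dx <- p1 / dp
    x <- x - dx
    if (max(abs(dx)) < 1e-15) break
  }
  list(x = x, w = 2 / ((1 - x^2) * dp^2))
}

#' Count 26-connected foreground components
#'
#' Flood fill over the 26-neighborhood; intended for small phantom grids.
#'
#' @param mask A [binary_mask()].
#' @return Number of connected components.
#' @export
count_components <- function(mask) {
  v <- mask$values
  d <- dim(v)
  lab <- array(0L, d)
  fg <- which(v)
  comp <- 0L
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (s in fg) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      cand <- sweep(nb, 2, as.integer(ci), "+")
      keep <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[keep, , drop = FALSE]
      lin <- cand[, 1] + d[1] * (cand[, 2] - 1L) + d[1] * d[2] * (cand[, 3] - 1L)
      lin <- lin[v[lin] & lab[lin] == 0L]
      lab[lin] <- comp
      queue <- c(queue, lin)
    }
  }
  comp
}
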