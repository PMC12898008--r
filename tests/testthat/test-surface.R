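test_that("the cube-corner hull has 8 vertices and 12 watertight faces", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 10
  for (shrink in c(0, 1)) {
    s <- reconstruct_surface(cube, shrink)
    expect_equal(nrow(s$vertices), 8)
    expect_equal(nrow(s$faces), 12)
    expect_true(is_watertight(s))
    expect_equal(mesh_volume(s), 1000, tolerance = 1e-9)
    expect_equal(surface_area(s), 600, tolerance = 1e-9)
  }
})

test_that("surfaces are watertight genus-0 meshes enclosing their points", {
  set.seed(7)
  n <- 1500
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 10
  s <- reconstruct_surface(u, 1)
  expect_true(is_watertight(s))
  nv <- nrow(s$vertices); nf <- nrow(s$faces)
  ne <- nf * 3 / 2
  expect_equal(nv - ne + nf, 2)            # Euler characteristic of a sphere
  # no degenerate faces
  v <- s$vertices; f <- s$faces
  a <- v[f[, 2], ] - v[f[, 1], ]; b <- v[f[, 3], ] - v[f[, 1], ]
  areas <- 0.5 * sqrt(rowSums(cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                    a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                    a[, 1] * b[, 2] - a[, 2] * b[, 1])^2))
  expect_gt(min(areas), 0)
  # every input point is a vertex of the supporting complex (hence enclosed)
  expect_length(setdiff(seq_len(nrow(s$points)),
                        unique(as.integer(s$tets))), 0)
  expect_true(all(surface_contains(s, u[sample(n, 100), ], tol = 1e-6)))
})

test_that("a dense spherical cloud reconstructs to the analytic area", {
  set.seed(12)
  n <- 4000
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 10
  s <- reconstruct_surface(u, 1)
  expect_lt(abs(surface_area(s) / (4 * pi * 100) - 1), 0.05)
  expect_lt(abs(mesh_volume(s) / (4 / 3 * pi * 1000) - 1), 0.05)
})

test_that("mesh volume is monotone non-increasing in shrink", {
  ph <- make_phantom("two_lobe", grid = image_grid(c(36, 24, 24), 1),
                     centers = rbind(c(11, 12, 12), c(24, 12, 12)),
                     radii = c(6, 6))
  reg <- generate_dangerous_region(ph$tumor, margin_mm = 3, pad_mm = 5,
                                   dense_spacing = c(1, 1, 1))
  vols <- vapply(c(0, 0.5, 1), function(sh)
    mesh_volume(reconstruct_surface(reg$boundary_points, sh)), numeric(1))
  expect_true(all(diff(vols) <= 1e-9))
  # and the shrink-1 surface stays watertight with all points kept
  s1 <- reconstruct_surface(reg$boundary_points, 1)
  expect_true(is_watertight(s1))
  expect_length(setdiff(seq_len(nrow(s1$points)),
                        unique(as.integer(s1$tets))), 0)
})

test_that("degenerate point sets are rejected, not repaired", {
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(reconstruct_surface(flat, 1), "degenerate-geometry")
  expect_error(reconstruct_surface(matrix(1, 3, 3), 1), "degenerate-geometry")
  dup <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  s <- reconstruct_surface(dup, 0)   # duplicates removed first
  expect_equal(nrow(s$vertices), 4)
})

test_that("plane clearance is signed, classified, and rigid-motion equivariant", {
  ph <- make_phantom("sphere", grid = image_grid(c(30, 30, 30), 1), radius = 5)
  reg <- generate_dangerous_region(ph$tumor, margin_mm = 4, pad_mm = 6)
  ctr <- ph$tumor$grid$origin + (ph$tumor$grid$shape - 1) / 2
  diag_d <- sqrt(sum(reg$dense_mask$grid$spacing^2))
  # region is approximately the r = 9 ball around ctr
  pl <- osteotomy_plane(ctr + c(14, 0, 0), c(1, 0, 0))
  cl <- plane_clearance(reg, pl)
  expect_equal(as.numeric(cl), 5, tolerance = diag_d)
  expect_true(attr(cl, "safe"))
  # intersecting plane: negative clearance, unsafe
  cl2 <- plane_clearance(reg, osteotomy_plane(ctr, c(0, 0, 1)))
  expect_lt(as.numeric(cl2), 0)
  expect_false(attr(cl2, "safe"))
  # tangent plane: clearance about zero
  cl3 <- plane_clearance(reg, osteotomy_plane(ctr + c(0, 9, 0), c(0, 1, 0)))
  expect_lt(abs(as.numeric(cl3)), diag_d)
  # axis permutation + translation of region and plane leaves clearance unchanged
  perm <- c(3, 1, 2)
  g <- reg$dense_mask$grid
  pg <- image_grid(g$shape[perm], g$spacing[perm], g$origin[perm] + c(5, -2, 8))
  pmask <- binary_mask(aperm(reg$dense_mask$values, perm), pg)
  preg <- structure(list(dense_mask = pmask,
                         boundary_points = NULL, provenance = NULL),
                    class = "dangerous_region")
  ppl <- osteotomy_plane((ctr + c(14, 0, 0))[perm] + c(5, -2, 8),
                         c(1, 0, 0)[perm])
  expect_equal(as.numeric(plane_clearance(preg, ppl)), as.numeric(cl),
               tolerance = 1e-9)
})

test_that("surface and point-cloud writers emit readable files", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  s <- reconstruct_surface(cube, 0)
  stl <- tempfile(fileext = ".stl")
  ply <- tempfile(fileext = ".ply")
  write_surface(s, stl)
  write_surface(s, ply)
  # binary STL: 84-byte header/count + 50 bytes per triangle
  expect_equal(file.size(stl), 84 + 50 * nrow(s$faces))
  lines <- readLines(ply)
  expect_equal(sum(grepl("^3 ", lines)), nrow(s$faces))
  pc <- tempfile(fileext = ".ply")
  write_point_cloud(cube, pc)
  expect_true(any(grepl("element vertex 8", readLines(pc))))
  unlink(c(stl, ply, pc))
})

test_that("plane plans round-trip through JSON", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(point = c(1, 2, 3), normal = c(0, 0, 2), name = "iliac"),
    list(point = c(0, 0, 0), normal = c(1, 0, 0))), f, auto_unbox = TRUE)
  planes <- read_plane_plan(f)
  expect_length(planes, 2)
  expect_equal(planes[[1]]$name, "iliac")
  expect_equal(sqrt(sum(planes[[1]]$normal^2)), 1, tolerance = 1e-12)
  unlink(f)
})
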