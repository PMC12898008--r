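test_that("voxelized phantom volumes track the closed forms", {
  ph <- make_phantom("sphere", grid = image_grid(c(24, 24, 24), 1), radius = 8)
  expect_lt(abs(mask_volume(ph$tumor) / ph$truth$volume - 1), 0.02)
  expect_equal(ph$truth$volume, 4 / 3 * pi * 512)
  el <- make_phantom("ellipsoid", grid = image_grid(c(30, 26, 22), 1),
                     radii = c(9, 7, 5))
  expect_lt(abs(mask_volume(el$tumor) / el$truth$volume - 1), 0.03)
})

test_that("voxelization error decreases as the grid refines", {
  errs <- vapply(c(2, 1, 0.5), function(sp) {
    n <- ceiling(22 / sp)
    ph <- make_phantom("sphere", grid = image_grid(rep(n, 3), sp), radius = 8)
    abs(mask_volume(ph$tumor) / ph$truth$volume - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("the ellipsoid Steiner coefficients reduce to the sphere closed form", {
  co <- osteomargin:::ellipsoid_steiner(c(8, 8, 8))
  expect_equal(co$area, 4 * pi * 64, tolerance = 1e-6)
  expect_equal(co$mean_curv_integral, 4 * pi * 8, tolerance = 1e-6)
  # dilated volume then matches the dilated-sphere closed form
  ph <- make_phantom("ellipsoid", grid = image_grid(c(24, 24, 24), 1),
                     radii = c(8, 8, 8))
  expect_equal(ph$truth$dilated_volume(20), 4 / 3 * pi * 28^3,
               tolerance = 1e-4)
})

test_that("disjoint lobes give two 26-connected components", {
  ph <- make_phantom("two_lobe", grid = image_grid(c(40, 24, 24), 1),
                     centers = rbind(c(10, 12, 12), c(30, 12, 12)),
                     radii = c(4, 4))
  expect_equal(count_components(ph$tumor), 2)
})

test_that("blob phantoms are seed-reproducible and leave the RNG untouched", {
  set.seed(99)
  before <- .Random.seed
  a <- make_phantom("blob", grid = image_grid(c(32, 32, 32), 1),
                    seed = 5, radius = 5)
  expect_identical(.Random.seed, before)
  b <- make_phantom("blob", grid = image_grid(c(32, 32, 32), 1),
                    seed = 5, radius = 5)
  expect_identical(a$tumor$values, b$tumor$values)
  d <- make_phantom("blob", grid = image_grid(c(32, 32, 32), 1),
                    seed = 6, radius = 5)
  expect_false(identical(a$tumor$values, d$tumor$values))
  expect_error(make_phantom("blob", grid = image_grid(c(32, 32, 32), 1)),
               "seed")
})

test_that("bone shells exclude the tumor and respect the angular sector", {
  ph <- make_phantom("sphere", grid = image_grid(c(40, 40, 40), 1), radius = 6,
                     bone = list(r_inner = 8, r_outer = 14,
                                 theta_max = pi / 2))
  expect_false(any(ph$tumor$values & ph$bone$values))
  expect_lt(abs(mask_volume(ph$bone) / ph$truth$bone_sector_volume - 1), 0.05)
  # sector: no bone below the equatorial plane (z < center)
  ctr <- ph$tumor$grid$origin + (ph$tumor$grid$shape - 1) / 2
  idx <- foreground_indices(ph$bone)
  z <- voxel_to_world(ph$bone$grid, idx)[, 3]
  expect_true(all(z >= ctr[3] - 1e-9))
})

test_that("a tumor that reaches the grid edge is rejected", {
  expect_error(make_phantom("sphere", grid = image_grid(c(12, 12, 12), 1),
                            radius = 8), "grid")
})
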