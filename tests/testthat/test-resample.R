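test_that("resampling to the same spacing is the identity", {
  m <- random_mask(c(10, 8, 6), c(1, 1.5, 2), p = 0.2, seed = 2)
  r <- resample_mask(m, m$grid$spacing)
  expect_identical(r$values, m$values)
  expect_equal(r$grid$origin, m$grid$origin)
})

test_that("a coarse solid cube refines to the enumerated interpolated interior", {
  # 2x2x2 solid at 2 mm spacing, voxel centers {2,4} per axis, refined to
  # 1 mm. Independent oracle: evaluate the separable hat-function
  # interpolant of the 0/1 field at every fine center by hand and apply the
  # membership rule (>= 0.5, ties foreground). Note the rule excludes the
  # continuous cube's edges and corners, where the trilinear product drops
  # to 0.25.
  g <- image_grid(c(4, 4, 4), 2)
  v <- array(FALSE, g$shape); v[2:3, 2:3, 2:3] <- TRUE
  fine <- resample_mask(binary_mask(v, g), 1)
  hat1d <- function(x) {
    # linear interpolation of the indicator of centers {2, 4} on the
    # coarse 1D lattice {0, 2, 4, 6}
    vals <- c(0, 1, 1, 0)
    vapply(x, function(t) {
      i <- floor(t / 2)
      frac <- t / 2 - i
      (1 - frac) * vals[i + 1] + if (frac > 0) frac * vals[i + 2] else 0
    }, numeric(1))
  }
  ax <- lapply(1:3, function(a) (seq_len(fine$grid$shape[a]) - 1) * 1)
  w <- lapply(ax, hat1d)
  val <- outer(outer(w[[1]], w[[2]]), w[[3]])
  inside <- val >= 0.5
  expect_equal(sum(fine$values), sum(inside))
  expect_identical(fine$values, inside)
  expect_equal(sum(inside), 81)  # 3^3 interior + 6 faces of 3^2
})

test_that("anisotropic CT spacing resamples to isotropic with geometry preserved", {
  g <- image_grid(c(24, 24, 10), c(0.8, 0.8, 3))
  ph <- make_phantom("sphere", grid = g, radius = 6)
  iso <- resample_mask(ph$tumor, 1)
  expect_equal(iso$grid$spacing, c(1, 1, 1))
  # world extent covered
  expect_true(all((iso$grid$shape - 1) * 1 >= (g$shape - 1) * g$spacing - 1e-9))
  # centroid moves less than one output voxel diagonal
  c0 <- colMeans(foreground_world(ph$tumor))
  c1 <- colMeans(foreground_world(iso))
  expect_lt(sqrt(sum((c1 - c0)^2)), sqrt(3))
  # volume roughly preserved
  expect_lt(abs(mask_volume(iso) / mask_volume(ph$tumor) - 1), 0.15)
})

test_that("resampling is translation-equivariant in world coordinates", {
  m <- random_mask(c(9, 9, 9), c(2, 2, 2), p = 0.15, seed = 5)
  shifted <- binary_mask(m$values,
                         image_grid(m$grid$shape, m$grid$spacing,
                                    m$grid$origin + c(7, -3, 11)))
  a <- resample_mask(m, 1)
  b <- resample_mask(shifted, 1)
  expect_identical(a$values, b$values)
  expect_equal(b$grid$origin - a$grid$origin, c(7, -3, 11))
  expect_error(resample_mask(m, c(1, 0, 1)), "target_spacing")
})
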