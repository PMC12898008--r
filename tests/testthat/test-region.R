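test_that("coarse thresholding reproduces closed-form neighborhood counts", {
  g <- image_grid(c(9, 9, 9), 1)
  v <- array(FALSE, g$shape); v[5, 5, 5] <- TRUE
  dm <- distance_transform(binary_mask(v, g))
  expect_identical(coarse_region(dm, 0)$values, v)          # margin 0 = tumor
  # integer offsets with i^2+j^2+k^2 <= 4 (enumerated: 33)
  off <- as.matrix(expand.grid(-4:4, -4:4, -4:4))
  expect_equal(sum(coarse_region(dm, 2)$values),
               sum(rowSums(off^2) <= 4))
  expect_equal(sum(coarse_region(dm, 2)$values), 33)
})

test_that("the fine ring matches brute-force enumeration of the (m-b, m] shell", {
  g <- image_grid(c(17, 17, 17), 0.5)
  v <- array(FALSE, g$shape); v[9, 9, 9] <- TRUE
  dm <- distance_transform(binary_mask(v, g))
  expect_equal(sum(fine_ring(dm, 2, 0)$values), 0)          # degenerate band
  ring <- fine_ring(dm, 2, 1)
  off <- as.matrix(expand.grid(-8:8, -8:8, -8:8)) * 0.5
  dd <- sqrt(rowSums(off^2))
  expect_equal(sum(ring$values), sum(dd > 1 & dd <= 2))
  expect_error(fine_ring(dm, 2, 3), "band_mm")
})

test_that("half-diagonal band default follows the source spacing", {
  # spacing (0.8, 0.8, 3): half diagonal = 0.5 * sqrt(0.64 + 0.64 + 9)
  g <- image_grid(c(16, 16, 8), c(0.8, 0.8, 3))
  ph <- make_phantom("sphere", grid = g, radius = 3)
  reg <- generate_dangerous_region(ph$tumor, margin_mm = 2.5, pad_mm = 3)
  expect_equal(reg$provenance$band_mm, 0.5 * sqrt(0.64 + 0.64 + 9),
               tolerance = 1e-12)
})

test_that("combining an empty ring reduces to the upsampled interior", {
  m <- random_mask(c(10, 10, 10), 1, p = 0.1, seed = 3)
  dm <- distance_transform(m)
  interior <- binary_mask(dm$values <= 2, dm$grid)
  dg <- image_grid(m$grid$shape * 2L - 1L, m$grid$spacing / 2, m$grid$origin)
  ring <- binary_mask(array(FALSE, dg$shape), dg)
  reg <- combine_regions(interior, ring, margin_spec(2, 0))
  up <- osteomargin:::upsample_nearest(interior$values, interior$grid, dg)
  expect_identical(reg$dense_mask$values, up)
  # mismatched world origins are a geometry error
  ring2 <- binary_mask(array(FALSE, dg$shape),
                       image_grid(dg$shape, dg$spacing, dg$origin + 5))
  expect_error(combine_regions(interior, ring2, margin_spec(2, 0)),
               "geometry")
})

test_that("the generated region contains the tumor and matches the oracle away from the margin shell", {
  for (seed in 1:4) {
    m <- random_mask(c(14, 14, 12), c(1, 1.2, 1.6), p = 0.03, seed = 20 + seed)
    margin <- 3
    reg <- generate_dangerous_region(m, margin_mm = margin, pad_mm = margin + 2)
    dg <- reg$dense_mask$grid
    crop <- crop_roi(m, margin + 2)$mask
    # containment of every tumor voxel center
    up <- osteomargin:::upsample_nearest(crop$values, crop$grid, dg)
    expect_false(any(up & !reg$dense_mask$values))
    # oracle agreement outside one dense diagonal of the isosurface
    orc <- oracle_region(crop, margin, dg)
    ax <- lapply(1:3, function(a) dg$origin[a] + (seq_len(dg$shape[a]) - 1) * dg$spacing[a])
    cen <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
    dd <- min_point_dist(cen, foreground_world(crop))
    dis <- as.vector(reg$dense_mask$values) != as.vector(orc$values)
    shell <- abs(dd - margin) <= sqrt(sum(dg$spacing^2))
    expect_equal(sum(dis & !shell), 0)
  }
})

test_that("regions grow monotonically with the margin and are translation-equivariant", {
  ph <- make_phantom("blob", grid = image_grid(c(36, 36, 36), 1),
                     seed = 11, radius = 5)
  regions <- lapply(c(3, 5, 8), function(m)
    generate_dangerous_region(ph$tumor, margin_mm = m, pad_mm = 10))
  for (i in 1:2) {
    a <- regions[[i]]$dense_mask; b <- regions[[i + 1]]$dense_mask
    expect_false(any(a$values & !b$values))
  }
  shifted <- binary_mask(ph$tumor$values,
                         image_grid(ph$tumor$grid$shape, c(1, 1, 1),
                                    ph$tumor$grid$origin + c(4, -1, 2)))
  r1 <- regions[[2]]
  r2 <- generate_dangerous_region(shifted, margin_mm = 5, pad_mm = 10)
  expect_identical(r2$dense_mask$values, r1$dense_mask$values)
  expect_equal(r2$dense_mask$grid$origin - r1$dense_mask$grid$origin,
               c(4, -1, 2))
})

test_that("margin zero recovers the tumor up to the half-voxel shell", {
  ph <- make_phantom("sphere", grid = image_grid(c(26, 26, 26), 1), radius = 6)
  reg <- generate_dangerous_region(ph$tumor, margin_mm = 0, pad_mm = 4)
  dg <- reg$dense_mask$grid
  crop <- crop_roi(ph$tumor, 4)$mask
  dis <- which(reg$dense_mask$values !=
                 osteomargin:::upsample_nearest(crop$values, crop$grid, dg))
  if (length(dis)) {
    cen <- voxel_to_world(dg, arrayInd(dis, dg$shape))
    dd <- min_point_dist(cen, foreground_world(crop))
    expect_lte(max(dd), 0.5 * sqrt(3))
  }
  succeed()
})

test_that("degenerate inputs raise classed pipeline errors", {
  g <- image_grid(c(10, 10, 10), 1)
  empty <- binary_mask(array(FALSE, g$shape), g)
  expect_error(generate_dangerous_region(empty, margin_mm = 2),
               class = "osteomargin_empty_foreground")
  # tumor flush against the grid edge cannot honor the pad
  v <- array(FALSE, g$shape); v[1:3, 5, 5] <- TRUE
  expect_error(generate_dangerous_region(binary_mask(v, g), margin_mm = 2,
                                         pad_mm = 5),
               class = "osteomargin_pad_too_small")
  expect_error(margin_spec(5, pad_mm = 3), "pad_mm")
})

test_that("the oracle on the tumor's own grid reduces to thresholding", {
  m <- random_mask(c(12, 12, 12), c(1, 1, 2), p = 0.05, seed = 31)
  expect_identical(oracle_region(m, 0)$values, m$values)
  d <- distance_transform(m)
  expect_identical(oracle_region(m, 2.5)$values, d$values <= 2.5)
})
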