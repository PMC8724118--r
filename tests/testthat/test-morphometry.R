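test_that("bone volume fraction is an exact voxel count and rotation invariant", {
  v <- binary_volume(array(TRUE, c(4, 4, 4)), 80)
  expect_identical(bone_volume_fraction(v), 1)
  d <- c(16, 16, 16)
  z <- slice.index(array(0, d), 1); y <- slice.index(array(0, d), 2)
  x <- slice.index(array(0, d), 3)
  ck <- binary_volume(array((z + y + x) %% 2 == 0, d), 80)
  expect_identical(bone_volume_fraction(ck), 0.5)

  s <- make_phantom("sphere", shape = 48, radius = 15)
  expect_identical(bone_volume_fraction(s), sum(s$grid) / length(s$grid))
  # axis permutations and 90-degree rotations leave BV/TV unchanged
  g <- std_phantom(shape = 24)$grid
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    vp <- binary_volume(aperm(g, perm), 80)
    expect_identical(bone_volume_fraction(vp),
                     bone_volume_fraction(binary_volume(g, 80)))
  }
  rot <- aperm(g[, , dim(g)[3]:1], c(1, 3, 2)) # 90 deg about z
  expect_identical(bone_volume_fraction(binary_volume(rot, 80)),
                   bone_volume_fraction(binary_volume(g, 80)))
})

test_that("triangulated surface area matches analytic sphere and slab areas", {
  v <- make_phantom("sphere", shape = 64, radius = 20, voxel_size_um = 1000)
  bs <- bone_surface_density(v) # 1/mm with 1 mm voxels
  area <- bs * 64^3
  expect_lt(abs(area - 4 * pi * 20^2) / (4 * pi * 20^2), 0.03)

  # slab spanning the volume: two faces, clipped boundary faces excluded
  s <- make_phantom("slab", shape = 96, thickness = 10, voxel_size_um = 1000)
  area_s <- bone_surface_density(s) * 96^3
  expect_lt(abs(area_s - 2 * 96^2) / (2 * 96^2), 0.03)

  empty <- binary_volume(array(FALSE, c(8, 8, 8)), 80)
  expect_warning(bs0 <- bone_surface_density(empty), "empty")
  expect_identical(bs0, 0)
})

test_that("local thickness recovers slab, cylinder and single-voxel diameters", {
  s <- make_phantom("slab", shape = 32, thickness = 10, axis = "z",
                    voxel_size_um = 1)
  th <- local_thickness(s, "foreground")
  expect_equal(th$stats$median, 10, tolerance = 1e-9)
  expect_equal(th$stats$max, 10, tolerance = 1e-9)

  d <- c(40, 40, 40); ctr <- (40 - 1) / 2
  y <- slice.index(array(0, d), 2) - 1; x <- slice.index(array(0, d), 3) - 1
  cyl <- binary_volume(array((y - ctr)^2 + (x - ctr)^2 <= 8^2, d), 1)
  interior <- local_thickness(cyl, "foreground")$stats$max
  expect_lt(abs(interior - 16), 1 + 1e-9)

  # single voxel: the centre-to-centre EDT convention reports 2 voxels,
  # within the documented +-1 voxel granularity of the method
  g <- array(FALSE, c(5, 5, 5)); g[3, 3, 3] <- TRUE
  single <- local_thickness(binary_volume(g, 1), "foreground")
  expect_equal(single$stats$mean, 2)
  expect_lt(abs(single$stats$mean - 1), 1 + 1e-9)
  expect_error(local_thickness(binary_volume(g, 1), "background"), NA)
  expect_error(local_thickness(binary_volume(!array(FALSE, c(4, 4, 4)), 1),
                               "background"), "empty")
})

test_that("thickness of a phase equals spacing of the complemented volume", {
  v <- std_phantom(shape = 24)
  comp <- binary_volume(!v$grid, v$voxel_size_um)
  a <- local_thickness(v, "foreground")$stats
  b <- local_thickness(comp, "background")$stats
  expect_equal(a$mean, b$mean, tolerance = 1e-12)
  expect_equal(a$max, b$max, tolerance = 1e-12)
})

test_that("connectivity density follows the Euler characteristic of canonical solids", {
  b <- make_phantom("sphere", shape = 32, radius = 10, voxel_size_um = 1000)
  cd <- connectivity_density(b)
  expect_equal(attr(cd, "euler"), 1)
  expect_equal(as.numeric(cd), 0)
  expect_identical(attr(cd, "n_components"), 1L)

  d <- c(40, 40, 40); ctr <- (40 - 1) / 2
  z <- slice.index(array(0, d), 1) - 1; y <- slice.index(array(0, d), 2) - 1
  x <- slice.index(array(0, d), 3) - 1
  torus <- binary_volume(
    array((sqrt((x - ctr)^2 + (y - ctr)^2) - 10)^2 + (z - ctr)^2 <= 4^2, d),
    1000)
  cdt <- connectivity_density(torus)
  expect_equal(attr(cdt, "euler"), 0)
  expect_equal(as.numeric(cdt), 1 / 40^3)
})

test_that("rod-lattice connectivity matches the graph Betti-number oracle", {
  for (n in 2:4) {
    rl <- make_phantom("rod_lattice", shape = 40, n_nodes = n, rod_radius = 1,
                       spacing = 8, voxel_size_um = 1000)
    cd <- connectivity_density(rl)
    betti1 <- 3 * n^2 * (n - 1) - n^3 + 1 # edges - nodes + 1 of the lattice graph
    expect_equal(1 - attr(cd, "euler"), betti1)
    expect_identical(attr(cd, "n_components"), 1L)
    expect_equal(as.numeric(cd), betti1 / 40^3)
  }
})

test_that("ellipsoid factor separates spheres, rods and plates", {
  b <- make_phantom("sphere", shape = 48, radius = 16, voxel_size_um = 1)
  ef_sphere <- ellipsoid_factor(b, n_seeds = 30, seed = 2)
  expect_lt(abs(ef_sphere$stats$mean), 0.05)

  d <- c(48, 48, 48)
  y <- slice.index(array(0, d), 2) - 1; x <- slice.index(array(0, d), 3) - 1
  rod <- binary_volume(array((y - 23.5)^2 + (x - 23.5)^2 <= 3^2, d), 1)
  ef_rod <- ellipsoid_factor(rod, n_seeds = 25, seed = 2)
  expect_gt(ef_rod$stats$median, 0.5)

  plate <- make_phantom("slab", shape = 48, thickness = 3, voxel_size_um = 1)
  ef_plate <- ellipsoid_factor(plate, n_seeds = 25, seed = 2)
  expect_lt(ef_plate$stats$median, -0.5)

  # EF always lies in [-1, 1]
  g <- std_phantom(shape = 32)
  ef_g <- ellipsoid_factor(g, n_seeds = 40, seed = 3)
  expect_true(all(ef_g$ef >= -1 & ef_g$ef <= 1))

  expect_identical(ef_value(2, 2, 2), 0)
  expect_error(ef_value(3, 2, 1), "a <= b <= c")
})

test_that("surface-fraction model vanishes at both density extremes and peaks at 1/2", {
  expect_identical(surface_model_predict(0, 14.55), 0)
  expect_identical(surface_model_predict(1, 14.55), 0)
  expect_identical(surface_model_predict(0.5, 14.55), 14.55 * 0.25)
  x <- seq(0, 1, by = 0.01)
  y <- surface_model_predict(x, 3)
  expect_equal(x[which.max(y)], 0.5)
  expect_equal(y, rev(y), tolerance = 1e-12) # symmetry about 1/2
  expect_error(surface_model_predict(1.2, 1), "0, 1")
})
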