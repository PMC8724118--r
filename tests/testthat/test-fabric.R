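test_that("MIL crossings match the brute-force voxel-walk oracle exactly", {
  v <- make_phantom("grf_trabecular", shape = 16, bvtv = 0.25, seed = 13,
                    voxel_size_um = 80)
  dirs <- trabfab:::hemisphere_directions(15, seed = 4)
  mil <- sample_mil(v, directions = dirs, line_spacing = 2, dither = FALSE)
  oracle <- mil_walk_oracle(v, dirs, spacing = 2, step = 0.5)
  keep <- oracle[, 2] / 2 > 0
  expect_equal(sum(!keep), attr(mil, "n_dropped"))
  expect_equal(mil$n_intercepts, oracle[keep, 2] / 2)
  expect_equal(mil$length_mm, oracle[keep, 1] * 80 / 1000)
  expect_equal(mil$mil_mm,
               oracle[keep, 1] * 80 / 1000 / (oracle[keep, 2] / 2))
})

test_that("MIL along the plate normal recovers the plate period", {
  # period s, thickness t: one intercept pair per period -> MIL = s.
  # Crop so the plates sit interior (a plate touching the volume face loses
  # one boundary crossing and would bias the estimate).
  big <- make_phantom("parallel_plates", shape = 72, thickness = 2,
                      period = 8, axis = "z", voxel_size_um = 1000)
  v <- crop_cube(big, c(4, 4, 4), 64)
  dirs <- rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0),
                trabfab:::hemisphere_directions(12, seed = 1))
  mil <- sample_mil(v, directions = dirs, line_spacing = 2, seed = 2)
  expect_lt(abs(mil$mil_mm[1] - 8) / 8, 0.05)
})

test_that("isotropic volumes have nearly direction-independent MIL", {
  # isotropic microstructure with resolved (multi-voxel) features; voxel-
  # scale Boolean noise sits below the marching resolution of any MIL
  # sampler and is excluded by design (see the methods vignette)
  v <- make_phantom("grf_trabecular", shape = 96, bvtv = 0.15,
                    stretch = c(1, 1, 1), seed = 21)
  mil <- sample_mil(v, n_directions = 400, line_spacing = 2, seed = 3)
  expect_lt(max(mil$mil_mm) / min(mil$mil_mm), 1.2)
})

test_that("tensor fit is exact on noiseless ellipsoidal data and equivariant", {
  M <- matrix(c(4, 0.3, -0.2, 0.3, 2, 0.1, -0.2, 0.1, 1), 3, 3)
  dirs <- trabfab:::hemisphere_directions(50, seed = 6)
  milv <- 1 / sqrt(rowSums((dirs %*% M) * dirs))
  df <- data.frame(dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
                   mil_mm = milv)
  fit <- fit_anisotropy_tensor(df)
  expect_lt(max(abs(fit$m - M)) / max(abs(M)), 1e-10)

  # constant MIL r -> M = I / r^2
  dfc <- df; dfc$mil_mm <- 2
  fitc <- fit_anisotropy_tensor(dfc)
  expect_equal(fitc$m, diag(3) / 4, tolerance = 1e-10)

  # rotating the directions rotates the tensor: R M R'
  R <- trabfab:::with_seed(9, trabfab:::random_rotation())
  dirs_r <- dirs %*% t(R)
  df_r <- data.frame(dx = dirs_r[, 1], dy = dirs_r[, 2], dz = dirs_r[, 3],
                     mil_mm = milv) # same MIL values at rotated directions
  fit_r <- fit_anisotropy_tensor(df_r)
  expect_lt(max(abs(fit_r$m - R %*% M %*% t(R))), 1e-9)
})

test_that("degree of anisotropy follows its eigenvalue definition", {
  t1 <- list(eigenvalues = c(0.326, 0.617, 0.731))
  expect_equal(degree_of_anisotropy(t1), 1 - 0.326 / 0.731, tolerance = 1e-12)
  expect_equal(round(degree_of_anisotropy(t1), 3), 0.554)
  expect_identical(degree_of_anisotropy(list(eigenvalues = c(2, 2, 2))), 0)
  expect_gt(degree_of_anisotropy(list(eigenvalues = c(1e-9, 1, 1))), 1 - 1e-8)
  # DA is invariant under uniform scaling of all MIL values
  expect_equal(degree_of_anisotropy(list(eigenvalues = 7 * c(0.3, 0.5, 0.9))),
               degree_of_anisotropy(list(eigenvalues = c(0.3, 0.5, 0.9))))
})

test_that("fabric tensor is the inverse square root with unit-sum eigenvalues", {
  m <- diag(c(4, 1, 1))
  t_ <- fit_anisotropy_tensor(local({
    dirs <- trabfab:::hemisphere_directions(40, seed = 2)
    data.frame(dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
               mil_mm = 1 / sqrt(rowSums((dirs %*% m) * dirs)))
  }))
  f <- fabric_from_anisotropy(t_)
  expect_equal(f$a_eigenvalues, c(1, 1, 0.5), tolerance = 1e-9)
  expect_equal(f$lambda, c(0.4, 0.4, 0.2), tolerance = 1e-9)
  expect_true(f$degenerate)

  # identity -> isotropic fabric
  fi <- fabric_from_anisotropy(
    structure(list(eigenvalues = c(1, 1, 1), eigenvectors = diag(3)),
              class = "anisotropy_tensor"))
  expect_equal(fi$a, diag(3))
  expect_equal(fi$lambda, rep(1 / 3, 3))

  # unit sum and orthonormality hold on measured fabric
  v <- std_phantom(shape = 32)
  f2 <- measure_fabric(v, n_directions = 300, line_spacing = 2, seed = 1)
  expect_lt(abs(sum(f2$lambda) - 1), 1e-12)
  expect_lt(max(abs(crossprod(f2$eigenvectors) - diag(3))), 1e-9)
  expect_true(f2$da >= 0 && f2$da < 1)
})

test_that("orientation angles are direction cosines folded into [0, 90]", {
  mk <- function(e1) {
    # build a fabric_result-like orientation via a rotation carrying z to e1
    R <- trabfab:::rotation_z_to(e1)
    vecs <- R[, c(3, 1, 2)]
    structure(list(a_eigenvalues = c(2, 1.5, 1), eigenvectors = vecs,
                   lambda = c(2, 1.5, 1) / 4.5, da = 0.5,
                   angles_deg = setNames(acos(pmin(1, abs(vecs[, 1]))) * 180 / pi,
                                         c("alpha", "beta", "gamma")),
                   degenerate = FALSE), class = "fabric_result")
  }
  expect_equal(orientation_angles(mk(c(0, 0, 1)))[["gamma"]], 0)
  e1 <- c(0, sin(7.4 * pi / 180), cos(7.4 * pi / 180))
  expect_equal(orientation_angles(mk(e1))[["gamma"]], 7.4, tolerance = 1e-9)
  expect_equal(orientation_angles(mk(c(0, 0, -1)))[["gamma"]], 0) # sign-folded
})

test_that("measured fabric is equivariant under lattice 90-degree rotation", {
  v <- std_phantom(shape = 48, seed = 17)
  # rotate volume 90 degrees about x (z -> y)
  g <- v$grid
  gr <- aperm(g[dim(g)[1]:1, , ], c(2, 1, 3))
  vr <- binary_volume(gr, v$voxel_size_um)
  f <- measure_fabric(v, n_directions = 600, line_spacing = 2, seed = 1)
  fr <- measure_fabric(vr, n_directions = 600, line_spacing = 2, seed = 1)
  expect_equal(fr$a_eigenvalues, f$a_eigenvalues, tolerance = 0.02)
  # principal axis (z for this phantom) maps to y
  expect_lt(acos(min(1, abs(f$eigenvectors[3, 1]))) * 180 / pi, 6)
  expect_lt(acos(min(1, abs(fr$eigenvectors[2, 1]))) * 180 / pi, 6)
})

test_that("doubling the direction count leaves DA stable", {
  v <- std_phantom(shape = 48)
  f1 <- measure_fabric(v, n_directions = 500, line_spacing = 2, seed = 1)
  f2 <- measure_fabric(v, n_directions = 1000, line_spacing = 2, seed = 1)
  expect_lt(abs(f1$da - f2$da), 0.02)
})

test_that("degenerate inputs are rejected cleanly", {
  full <- binary_volume(array(TRUE, c(16, 16, 16)), 80)
  expect_error(sample_mil(full, 50), "both phases")
  v <- std_phantom(shape = 24)
  expect_error(sample_mil(v, n_directions = 5), ">= 9")
  expect_error(fit_anisotropy_tensor(data.frame(dx = 1, dy = 0, dz = 0,
                                                mil_mm = 1)), "9")
})
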