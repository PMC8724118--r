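test_that("volume-fraction functions obey their closed-form limits", {
  k <- kabel_constants()
  expect_equal(k_functions(0, k), k$k_a)
  expect_equal(k_functions(1, k), k$k_a + k$k_b)
  # direct evaluation at the cohort-mean volume fraction
  expect_equal(k_functions(0.133, k)[1],
               -6.523e-3 + 6.238e-1 * 0.133^1.6, tolerance = 1e-12)
  expect_equal(k_functions(0.133, k)[1], 1.82e-2, tolerance = 2e-3)
  expect_error(k_functions(1.5, k), "0, 1")
})

test_that("stiffness assembly matches the independent term-by-term transcription", {
  k <- kabel_constants()
  lam <- c(0.25, 0.33, 0.42)
  el <- assemble_stiffness(lam, 0.15, k)
  oracle <- eq8_transcription_oracle(lam, 0.15, k)
  # el axes are E-ordered; undo the permutation for comparison
  perm <- el$axis_permutation
  back <- matrix(0, 6, 6)
  back[perm, perm] <- el$c_voigt[1:3, 1:3]
  for (s in 1:3) back[3 + perm[s], 3 + perm[s]] <- el$c_voigt[3 + s, 3 + s]
  expect_lt(max(abs(back - oracle)), 1e-12)
  expect_lt(max(abs(el$c_voigt - t(el$c_voigt))), 1e-12 * max(abs(el$c_voigt)))
})

test_that("equal eigenvalues give cubic symmetry and permutations permute axes", {
  k <- kabel_constants()
  el <- assemble_stiffness(rep(1 / 3, 3), 0.133, k)
  C <- el$c_voigt
  expect_equal(C[1, 1], C[2, 2], tolerance = 1e-14)
  expect_equal(C[2, 2], C[3, 3], tolerance = 1e-14)
  expect_equal(C[1, 2], C[1, 3], tolerance = 1e-14)
  expect_equal(C[4, 4], C[6, 6], tolerance = 1e-14)

  lam <- c(0.2, 0.35, 0.45)
  a <- assemble_stiffness(lam, 0.15, k)
  b <- assemble_stiffness(lam[c(3, 1, 2)], 0.15, k)
  # axis ordering is by Young's modulus, so both orderings must agree
  expect_equal(a$c_voigt, b$c_voigt, tolerance = 1e-12)
  expect_equal(a$lambda, b$lambda)
})

test_that("axes are labelled so that z' carries the largest Young's modulus", {
  el <- assemble_stiffness(c(0.42, 0.33, 0.25), 0.133, kabel_constants())
  expect_true(el$E[["E_x"]] <= el$E[["E_y"]])
  expect_true(el$E[["E_y"]] <= el$E[["E_z"]])
  expect_equal(el$lambda, sort(el$lambda)) # larger lambda -> stiffer axis
})

test_that("engineering constants recover closed-form isotropic elasticity", {
  C <- isotropic_voigt(15, 0.3)
  e <- engineering_constants(as_elasticity(C, Et_GPa = 1))
  expect_equal(unname(e$E), rep(15, 3), tolerance = 1e-12)
  expect_equal(unname(e$G), rep(15 / (2 * 1.3), 3), tolerance = 1e-12)
  expect_equal(unname(e$nu), rep(0.3, 6), tolerance = 1e-12)

  # diagonal stiffness: no coupling, E_i = C_ii, nu = 0
  D <- diag(c(2, 3, 4, 1, 1, 1))
  ed <- engineering_constants(as_elasticity(D))
  expect_equal(unname(ed$E), c(2, 3, 4))
  expect_equal(unname(ed$nu), rep(0, 6))

  bad <- as_elasticity(diag(c(-1, 1, 1, 1, 1, 1)))
  expect_error(engineering_constants(bad), "positive definite")
})

test_that("Poisson reciprocity holds to 1e-10 on study-range stiffnesses", {
  k <- kabel_constants()
  for (lam1 in c(0.36, 0.40, 0.44)) for (bv in c(0.082, 0.133, 0.194)) {
    rest <- 1 - lam1
    lam <- c(rest * 0.48, rest * 0.52, lam1)
    el <- assemble_stiffness(lam, bv, k)
    expect_true(el$valid)
    E <- el$E; nu <- el$nu
    expect_lt(abs(nu[["nu_yx"]] / E[["E_y"]] - nu[["nu_xy"]] / E[["E_x"]]) /
                abs(nu[["nu_xy"]] / E[["E_x"]]), 1e-10)
    expect_lt(abs(nu[["nu_zx"]] / E[["E_z"]] - nu[["nu_xz"]] / E[["E_x"]]) /
                abs(nu[["nu_xz"]] / E[["E_x"]]), 1e-10)
    expect_lt(abs(nu[["nu_zy"]] / E[["E_z"]] - nu[["nu_yz"]] / E[["E_y"]]) /
                abs(nu[["nu_yz"]] / E[["E_y"]]), 1e-10)
  }
})

test_that("compliance reassembled from the engineering constants reproduces S", {
  el <- assemble_stiffness(c(0.28, 0.30, 0.42), 0.15, kabel_constants())
  E <- el$E; G <- el$G; nu <- el$nu
  S <- matrix(0, 6, 6)
  diag(S) <- c(1 / E, 1 / G)
  S[1, 2] <- S[2, 1] <- -nu[["nu_xy"]] / E[["E_x"]]
  S[1, 3] <- S[3, 1] <- -nu[["nu_xz"]] / E[["E_x"]]
  S[2, 3] <- S[3, 2] <- -nu[["nu_yz"]] / E[["E_y"]]
  expect_lt(max(abs(S - el$s_voigt)), 1e-10 * max(abs(el$s_voigt)))
})

test_that("directional modulus matches the principal moduli and frame indifference", {
  el <- assemble_stiffness(c(0.28, 0.30, 0.42), 0.133, kabel_constants())
  expect_equal(directional_modulus(el, c(1, 0, 0)), el$E[["E_x"]],
               tolerance = 1e-12)
  expect_equal(directional_modulus(el, c(0, 1, 0)), el$E[["E_y"]],
               tolerance = 1e-12)
  expect_equal(directional_modulus(el, c(0, 0, 1)), el$E[["E_z"]],
               tolerance = 1e-12)

  # isotropic material: constant over random directions
  iso <- as_elasticity(isotropic_voigt(15, 0.3))
  dirs <- trabfab:::hemisphere_directions(200, seed = 3)
  ei <- directional_modulus(iso, dirs)
  expect_lt(diff(range(ei)) / 15, 1e-10)

  # the maximum over a dense sphere grid sits near the stiffest axis
  grid <- trabfab:::sphere_points(10000)
  vals <- directional_modulus(el, grid)
  nmax <- grid[which.max(vals), ]
  ang <- acos(min(1, abs(nmax[3]))) * 180 / pi
  expect_lt(ang, 3)

  expect_error(directional_modulus(el, c(0, 0, 0)), "nonzero")
})

test_that("tensor rotation is exact for permutations and invertible", {
  el <- assemble_stiffness(c(0.28, 0.30, 0.42), 0.15, kabel_constants())
  C <- el$c_voigt
  expect_equal(rotate_to_global(el, diag(3)), C, tolerance = 1e-14)

  # 90-degree rotation about z swaps the x and y material axes
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  Cr <- rotate_to_global(el, Rz)
  expect_equal(Cr[1, 1], C[2, 2], tolerance = 1e-12)
  expect_equal(Cr[2, 2], C[1, 1], tolerance = 1e-12)
  expect_equal(Cr[4, 4], C[5, 5], tolerance = 1e-12)
  expect_equal(Cr[3, 3], C[3, 3], tolerance = 1e-12)

  # random rotation round trip
  R <- trabfab:::with_seed(5, trabfab:::random_rotation())
  Cr2 <- rotate_to_global(el, R)
  back <- rotate_to_global(Cr2, t(R))
  expect_lt(max(abs(back - C)), 1e-12 * max(abs(C)))

  # frame indifference of E(n)
  n <- c(0.2, -0.5, 0.84); n <- n / sqrt(sum(n^2))
  e_rot <- as_elasticity(rotate_to_global(el, R))
  expect_lt(abs(directional_modulus(e_rot, as.vector(R %*% n)) -
                  directional_modulus(el, n)) /
              directional_modulus(el, n), 1e-10)

  expect_error(rotate_to_global(el, matrix(1, 3, 3)), "orthonormal")
})

test_that("moduli increase with volume fraction at fixed fabric over the study range", {
  k <- kabel_constants()
  lam <- c(0.28, 0.30, 0.42)
  bv <- seq(0.082, 0.194, length.out = 8)
  res <- t(vapply(bv, function(b) {
    el <- assemble_stiffness(lam, b, k)
    c(el$E, el$G)
  }, numeric(6)))
  for (j in 1:6) expect_true(all(diff(res[, j]) > 0))
})

test_that("printed-variant constants are exposed and flagged non-positive-definite", {
  kp <- kabel_constants("printed")
  expect_equal(kp$k_b[4], -1.159e1)
  expect_equal(kp$k_b[8], -8.001)
  el <- suppressWarnings(assemble_stiffness(c(0.28, 0.30, 0.42), 0.133, kp))
  expect_false(el$valid)
  expect_warning(assemble_stiffness(rep(1 / 3, 3), 0.133, kp),
                 "positive definite")
  # the audit reports the non-PD region rather than erroring
  audit <- audit_positive_definiteness(kp, bv_tv = c(0.082, 0.133),
                                       lambda1 = c(1 / 3, 0.40), n_shape = 2)
  expect_true(all(!audit$valid))
  audit_c <- audit_positive_definiteness(kabel_constants(),
                                         bv_tv = c(0.082, 0.133, 0.194),
                                         lambda1 = seq(1 / 3, 0.44, 0.02),
                                         n_shape = 3)
  # corrected constants: fully positive definite up to lambda1 ~ 0.40,
  # with documented failures only at extreme anisotropy
  expect_true(all(audit_c$valid[audit_c$lambda1 < 0.40]))
  expect_true(mean(audit_c$valid) > 0.8)
  expect_true(all(is.finite(audit_c$min_eigenvalue)))
})

test_that("the corrected constants reproduce the expected cohort stiffness scale", {
  # mean fabric (from the cohort-mean anisotropy eigenvalues) and mean BV/TV
  D <- c(0.326, 0.617, 0.731)
  a <- D^(-0.5); lam <- a / sum(a)
  el <- assemble_stiffness(lam, 0.133, kabel_constants())
  expect_true(el$valid)
  # normalized moduli in the reported cohort ballpark (means of a nonlinear
  # map evaluated at mean inputs: generous 25% band)
  expect_lt(abs(el$E[["E_z"]] - 47.60e-3) / 47.60e-3, 0.25)
  expect_lt(abs(el$E[["E_y"]] - 15.76e-3) / 15.76e-3, 0.25)
  expect_lt(abs(el$G[["G_xy"]] - 5.46e-3) / 5.46e-3, 0.25)
  # and the z' extrapolation to solid bone exceeds the tissue modulus
  el1 <- assemble_stiffness(lam, 1, kabel_constants())
  expect_gt(el1$E_GPa[["E_z"]] , 15)
})
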