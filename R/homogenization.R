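# Fabric-elasticity homogenization: Cowin's orthotropic relations between
# the normalized fabric eigenvalues, the bone volume fraction and the 6x6
# stiffness in Voigt notation, with empirically fitted volume-fraction
# functions (Kabel micro-FE constants).

#' Volume-fraction function constants for the fabric-elasticity relations
#'
#' Loads the nine pairs `(k_ia, k_ib)` defining
#' `k_i = k_ia + k_ib * (BV/TV)^p`, the exponent `p` and the isotropic
#' tissue modulus `Et`.  Two variants ship with the package:
#' `"corrected"` (default; two sign corrections `k4b, k8b > 0` relative to
#' the printed source table, which restore positive definiteness over the
#' study domain and reproduce the reported cohort stiffness scale — see the
#' methods vignette and [audit_positive_definiteness()]) and `"printed"`
#' (the source table verbatim; negative definite everywhere, shipped for
#' audit).  A custom JSON file with fields `k_a`, `k_b`, `p`, `Et_GPa`
#' can be supplied instead.
#'
#' @param variant `"corrected"` or `"printed"`.
#' @param file optional path to a custom constants JSON file.
#' @param Et_GPa optional override of the tissue modulus (GPa).
#' @return A list of class `kabel_constants`.
#' @export
kabel_constants <- function(variant = c("corrected", "printed"), file = NULL,
                            Et_GPa = NULL) {
  if (is.null(file)) {
    variant <- match.arg(variant)
    file <- system.file("extdata",
                        paste0("kabel_constants_", variant, ".json"),
                        package = "trabfab", mustWork = TRUE)
  }
  k <- jsonlite::read_json(file, simplifyVector = TRUE)
  stopifnot(length(k$k_a) == 9, length(k$k_b) == 9, k$p > 0, k$Et_GPa > 0)
  if (!is.null(Et_GPa)) k$Et_GPa <- Et_GPa
  structure(list(name = k$name %||% basename(file), k_a = as.numeric(k$k_a),
                 k_b = as.numeric(k$k_b), p = as.numeric(k$p),
                 Et_GPa = as.numeric(k$Et_GPa)),
            class = "kabel_constants")
}

#' @export
print.kabel_constants <- function(x, ...) {
  cat("<kabel_constants> set:", x$name, sprintf(" p = %g, Et = %g GPa\n",
                                                x$p, x$Et_GPa))
  print(data.frame(i = 1:9, k_a = x$k_a, k_b = x$k_b), row.names = FALSE)
  invisible(x)
}

#' Evaluate the nine volume-fraction functions
#'
#' `k_i(BV/TV) = k_ia + k_ib * (BV/TV)^p`, i = 1..9.
#'
#' @param bv_tv bone volume fraction in \[0, 1\].
#' @param constants a [kabel_constants()] set.
#' @return Numeric vector of length 9.
#' @export
k_functions <- function(bv_tv, constants = kabel_constants()) {
  if (any(bv_tv < 0 | bv_tv > 1)) stop("`bv_tv` must lie in [0, 1]")
  constants$k_a + constants$k_b * bv_tv^constants$p
}

# Core of the orthotropic relations: 6x6 stiffness (units of Et) in the
# fabric eigenbasis, axes in the order the lambdas are given.
assemble_c_voigt <- function(lambda, k) {
  II <- lambda[1] * lambda[2] + lambda[1] * lambda[3] + lambda[2] * lambda[3]
  C <- matrix(0, 6, 6)
  for (i in 1:3)
    C[i, i] <- k[1] + 2 * k[6] + (k[2] + 2 * k[7]) * II +
      2 * (k[3] + 2 * k[8]) * lambda[i] +
      (2 * k[4] + k[5] + 4 * k[9]) * lambda[i]^2
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (pr in pairs) {
    i <- pr[1]; j <- pr[2]
    C[i, j] <- C[j, i] <- k[1] + k[2] * II + k[3] * (lambda[i] + lambda[j]) +
      k[4] * (lambda[i]^2 + lambda[j]^2) + k[5] * lambda[i] * lambda[j]
  }
  shear <- list(c(2, 3), c(1, 3), c(1, 2)) # Voigt 4, 5, 6
  for (s in 1:3) {
    i <- shear[[s]][1]; j <- shear[[s]][2]
    C[3 + s, 3 + s] <- k[6] + k[7] * II + k[8] * (lambda[i] + lambda[j]) +
      k[9] * (lambda[i]^2 + lambda[j]^2)
  }
  C
}

# Permute the material axes of an orthotropic Voigt stiffness: new axis a is
# old axis perm[a]; Voigt shear s is attached to the axis it excludes.
permute_axes_voigt <- function(C, perm) {
  out <- matrix(0, 6, 6)
  out[1:3, 1:3] <- C[perm, perm]
  for (s in 1:3) out[3 + s, 3 + s] <- C[3 + perm[s], 3 + perm[s]]
  out
}

#' Assemble the homogenized orthotropic stiffness
#'
#' Maps the normalized fabric eigenvalues and the bone volume fraction to
#' the 6x6 orthotropic stiffness in the fabric eigenbasis (Voigt order 11,
#' 22, 33, 23, 13, 12; engineering shear convention).  The material axes
#' `x', y', z'` are ordered so that `z'` carries the largest Young's
#' modulus; the returned `lambda` and `eigenvectors` follow that ordering.
#' A non-positive-definite result is returned with `valid = FALSE` and a
#' structured warning, never silently clipped.
#'
#' @param lambda three positive normalized fabric eigenvalues summing to 1
#'   (within 1e-9), in any order.
#' @param bv_tv bone volume fraction in \[0, 1\].
#' @param constants a [kabel_constants()] set.
#' @param eigenvectors optional 3x3 matrix whose columns are the fabric
#'   eigenvectors matching `lambda` (global frame); carried through the
#'   axis reordering for later rotation to volume axes.
#' @return An object of class `orthotropic_elasticity`: `c_voigt`
#'   (units of Et), `c_voigt_gpa`, `lambda`, `bv_tv`, `valid`,
#'   `eigenvalues` (of the Voigt matrix), plus — when valid — the
#'   engineering constants filled in by [engineering_constants()].
#' @export
assemble_stiffness <- function(lambda, bv_tv, constants = kabel_constants(),
                               eigenvectors = NULL) {
  if (length(lambda) != 3L || any(lambda <= 0))
    stop("`lambda` must be three positive values")
  if (abs(sum(lambda) - 1) > 1e-9)
    stop("`lambda` must sum to 1 (got ", format(sum(lambda)), ")")
  if (bv_tv < 0 || bv_tv > 1) stop("`bv_tv` must lie in [0, 1]")
  k <- k_functions(bv_tv, constants)
  C <- assemble_c_voigt(lambda, k)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  valid <- all(ev > 0)
  perm <- 1:3
  if (valid) {
    S <- solve(C)
    perm <- order(1 / diag(S)[1:3]) # ascending E -> axes x', y', z'
    C <- permute_axes_voigt(C, perm)
  } else {
    warning(structure(class = c("trabfab_not_pd", "warning", "condition"),
                      list(message = paste0(
                        "assembled stiffness is not positive definite ",
                        "(min eigenvalue ", format(min(ev), digits = 3),
                        "); engineering constants unavailable"),
                        call = sys.call(-1))))
  }
  out <- structure(list(
    c_voigt = C,
    c_voigt_gpa = C * constants$Et_GPa,
    lambda = lambda[perm],
    bv_tv = bv_tv,
    constants = constants,
    eigenvectors = if (!is.null(eigenvectors)) eigenvectors[, perm, drop = FALSE],
    axis_permutation = perm,
    eigenvalues = ev,
    valid = valid), class = "orthotropic_elasticity")
  if (valid) engineering_constants(out) else out
}

#' Engineering constants from an orthotropic stiffness
#'
#' Inverts the Voigt stiffness to the compliance `S = C^-1` (engineering
#' shear convention, so `G_i = 1/S_ii` for i = 4, 5, 6 literally) and reads
#' off the Young's moduli `E_i = 1/S_ii`, shear moduli and Poisson ratios
#' `nu_ij = -S_ij / S_ii`; the three dependent ratios satisfy the
#' reciprocity relations `nu_ji / E_j = nu_ij / E_i`.
#'
#' @param e an `orthotropic_elasticity` with `valid = TRUE`.
#' @return The completed `orthotropic_elasticity`: `s_voigt`, `E`
#'   (`E_x, E_y, E_z`, units of Et), `E_GPa`, `G` (`G_yz, G_xz, G_xy`),
#'   `G_GPa`, `nu` (named `nu_yz, nu_xz, nu_xy, nu_zy, nu_zx, nu_yx`).
#' @export
engineering_constants <- function(e) {
  stopifnot(inherits(e, "orthotropic_elasticity"))
  if (!isTRUE(e$valid))
    stop("stiffness is not positive definite; eigenvalues: ",
         paste(format(e$eigenvalues, digits = 3), collapse = ", "))
  S <- solve(e$c_voigt)
  E <- 1 / diag(S)[1:3]
  G <- 1 / diag(S)[4:6]
  nu <- c(nu_yz = -S[2, 3] / S[2, 2], nu_xz = -S[1, 3] / S[1, 1],
          nu_xy = -S[1, 2] / S[1, 1], nu_zy = -S[3, 2] / S[3, 3],
          nu_zx = -S[3, 1] / S[3, 3], nu_yx = -S[2, 1] / S[2, 2])
  Et <- e$constants$Et_GPa
  e$s_voigt <- S
  e$E <- setNames(E, c("E_x", "E_y", "E_z"))
  e$G <- setNames(G, c("G_yz", "G_xz", "G_xy"))
  e$E_GPa <- e$E * Et
  e$G_GPa <- e$G * Et
  e$nu <- nu
  e
}

#' @export
print.orthotropic_elasticity <- function(x, ...) {
  cat("<orthotropic_elasticity> BV/TV =", sprintf("%.4f", x$bv_tv),
      " lambda =", sprintf("%.4f", x$lambda), "\n")
  if (isTRUE(x$valid)) {
    cat(sprintf("  E (GPa): x' %.4f, y' %.4f, z' %.4f\n",
                x$E_GPa[1], x$E_GPa[2], x$E_GPa[3]))
    cat(sprintf("  G (GPa): y'z' %.4f, x'z' %.4f, x'y' %.4f\n",
                x$G_GPa[1], x$G_GPa[2], x$G_GPa[3]))
    cat("  nu:", paste(names(x$nu), sprintf("%.3f", x$nu)), "\n")
  } else {
    cat("  NOT positive definite (min eigenvalue ",
        format(min(x$eigenvalues), digits = 3), ")\n", sep = "")
  }
  invisible(x)
}

# Voigt index map and tensor<->Voigt conversions -----------------------------

voigt_pairs <- matrix(c(1, 1, 2, 2, 3, 3, 2, 3, 1, 3, 1, 2), ncol = 2,
                      byrow = TRUE)

# Full 3x3x3x3 stiffness tensor from engineering-Voigt stiffness.
stiffness_tensor <- function(Cv) {
  Ct <- array(0, c(3, 3, 3, 3))
  for (p in 1:6) for (q in 1:6) {
    i <- voigt_pairs[p, 1]; j <- voigt_pairs[p, 2]
    k <- voigt_pairs[q, 1]; l <- voigt_pairs[q, 2]
    Ct[i, j, k, l] <- Ct[j, i, k, l] <- Ct[i, j, l, k] <- Ct[j, i, l, k] <- Cv[p, q]
  }
  Ct
}

# Full compliance tensor (tensor shear convention) from engineering-Voigt
# compliance: S_t has factors 1, 1/2, 1/4 for 0, 1, 2 shear indices.
compliance_tensor <- function(Sv) {
  St <- array(0, c(3, 3, 3, 3))
  for (p in 1:6) for (q in 1:6) {
    fac <- 1
    if (p > 3) fac <- fac / 2
    if (q > 3) fac <- fac / 2
    i <- voigt_pairs[p, 1]; j <- voigt_pairs[p, 2]
    k <- voigt_pairs[q, 1]; l <- voigt_pairs[q, 2]
    v <- Sv[p, q] * fac
    St[i, j, k, l] <- St[j, i, k, l] <- St[i, j, l, k] <- St[j, i, l, k] <- v
  }
  St
}

#' Directional Young's modulus
#'
#' `E(n) = 1 / (n_i n_j n_k n_m S_ijkm)` with the full fourth-rank
#' compliance (tensor shear convention internally): the uniaxial stiffness
#' for an elongation test along the unit direction `n`.  Evaluated over the
#' sphere this is the classic directional-stiffness surface.
#'
#' @param e a valid `orthotropic_elasticity`.
#' @param n direction(s): length-3 vector or matrix with 3 columns
#'   (need not be normalized, but must be nonzero).
#' @param units `"Et"` (default, units of the tissue modulus) or `"GPa"`.
#' @return E(n), one value per direction.
#' @export
directional_modulus <- function(e, n, units = c("Et", "GPa")) {
  stopifnot(inherits(e, "orthotropic_elasticity"))
  units <- match.arg(units)
  if (!isTRUE(e$valid)) stop("stiffness is not positive definite")
  if (is.null(dim(n))) n <- matrix(n, ncol = 3)
  nrm <- sqrt(rowSums(n^2))
  if (any(nrm < 1e-300)) stop("direction must be a nonzero vector")
  n <- n / nrm
  St <- compliance_tensor(e$s_voigt %||% solve(e$c_voigt))
  vals <- apply(n, 1, function(v) {
    s <- 0
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
      s <- s + v[i] * v[j] * v[k] * v[l] * St[i, j, k, l]
    1 / s
  })
  if (units == "GPa") vals <- vals * e$constants$Et_GPa
  vals
}

#' Rotate an orthotropic stiffness to the volume axes
#'
#' Fourth-rank tensor rotation `C'_ijkl = R_ia R_jb R_kc R_ld C_abcd`: the
#' stiffness assembled in the fabric eigenbasis is expressed in the global
#' (volume) coordinate system whose axes the eigenvector matrix refers to.
#'
#' @param e a `orthotropic_elasticity` (rotates `c_voigt`), or a 6x6 Voigt
#'   stiffness matrix.
#' @param eigvecs orthonormal 3x3 matrix, columns = material axes
#'   (`x', y', z'`) expressed in the global frame; a reflection
#'   (det = -1) is fixed by flipping the third column.  Defaults to the
#'   eigenvectors stored in `e`.
#' @return The rotated 6x6 Voigt stiffness (same units as the input).
#' @export
rotate_to_global <- function(e, eigvecs = NULL) {
  Cv <- if (inherits(e, "orthotropic_elasticity")) {
    if (is.null(eigvecs)) eigvecs <- e$eigenvectors
    e$c_voigt
  } else as.matrix(e)
  if (is.null(eigvecs)) stop("no eigenvector matrix supplied")
  R <- as.matrix(eigvecs)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("`eigvecs` must be orthonormal")
  if (det(R) < 0) R[, 3] <- -R[, 3]
  Ct <- stiffness_tensor(Cv)
  dim(Ct) <- c(9, 9)
  RR <- kronecker(R, R)
  Cr <- RR %*% Ct %*% t(RR)
  dim(Cr) <- c(3, 3, 3, 3)
  out <- matrix(0, 6, 6)
  for (p in 1:6) for (q in 1:6)
    out[p, q] <- Cr[voigt_pairs[p, 1], voigt_pairs[p, 2],
                    voigt_pairs[q, 1], voigt_pairs[q, 2]]
  (out + t(out)) / 2
}

#' Positive-definiteness audit of the fabric-elasticity model
#'
#' Sweeps the study domain (BV/TV range times a grid of ordered normalized
#' eigenvalue triples up to a given anisotropy) and reports, for a constants
#' configuration, where the assembled stiffness is positive definite and
#' what stiffness scale it produces.  This is a report, not a gate: it
#' documents which constant configuration reproduces the expected cohort
#' stiffness magnitudes.
#'
#' @param constants a [kabel_constants()] set.
#' @param bv_tv volume fractions to sweep.
#' @param lambda1 largest normalized eigenvalues to sweep (>= 1/3).
#' @param n_shape intermediate-eigenvalue positions per `lambda1`.
#' @return A data.frame of class `pd_audit` with one row per combination:
#'   `bv_tv, lambda1, lambda2, lambda3, da_fabric, valid, min_eigenvalue,
#'   E_z` (units Et, NA when invalid).
#' @export
audit_positive_definiteness <- function(constants = kabel_constants(),
                                        bv_tv = seq(0.082, 0.194, by = 0.016),
                                        lambda1 = seq(1 / 3, 0.46, by = 0.02),
                                        n_shape = 4) {
  rows <- list()
  for (bv in bv_tv) for (l1 in lambda1) {
    rest <- 1 - l1
    l2_min <- rest / 2
    l2_max <- min(l1, rest) - 1e-9
    for (t in seq(0, 1, length.out = n_shape)) {
      l2 <- l2_min + t * (l2_max - l2_min)
      l3 <- rest - l2
      if (l3 <= 0 || l2 < l3 - 1e-12) next
      res <- suppressWarnings(
        assemble_stiffness(c(l3, l2, l1), bv, constants))
      rows[[length(rows) + 1]] <- data.frame(
        bv_tv = bv, lambda1 = l1, lambda2 = l2, lambda3 = l3,
        da_fabric = 1 - (l3 / l1)^2, # DA of the implied M eigenvalues
        valid = res$valid,
        min_eigenvalue = min(res$eigenvalues),
        E_z = if (res$valid) unname(res$E["E_z"]) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pd_audit", "data.frame")
  attr(out, "constants") <- constants$name
  out
}

#' @export
print.pd_audit <- function(x, ...) {
  cat("<pd_audit> constants:", attr(x, "constants"), "\n")
  cat(sprintf("  %d combinations, %.1f%% positive definite\n",
              nrow(x), 100 * mean(x$valid)))
  if (any(x$valid))
    cat(sprintf("  E_z'/Et over valid region: %.4g .. %.4g\n",
                min(x$E_z, na.rm = TRUE), max(x$E_z, na.rm = TRUE)))
  if (!all(x$valid)) {
    inv <- x[!x$valid, ]
    cat(sprintf("  non-PD region: lambda1 >= %.3f (%d rows)\n",
                min(inv$lambda1), nrow(inv)))
  }
  invisible(x)
}
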