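#' Sample mean intercept lengths (MIL)
#'
#' For each test direction a parallel grid of lines (spacing
#' `line_spacing` voxels, origin dithered from the seed) is marched through
#' the volume at half-voxel steps; bone/marrow boundary crossings are counted
#' along the in-volume parts of the lines.  The mean intercept length of a
#' direction is the total in-volume test-line length divided by the number of
#' intercepts (boundary-crossing pairs).  Directions with no intercepts are
#' dropped and counted.
#'
#' @param vol a [binary_volume()] containing both phases.
#' @param n_directions number of test directions (>= 9, the minimum to fit a
#'   symmetric second-rank tensor robustly); the study default is 5000.
#' @param line_spacing spacing of the parallel test lines in voxels.
#' @param seed RNG seed (direction set de-alignment and origin dither).
#' @param method direction sampling on the hemisphere: seeded
#'   low-discrepancy lattice (default) or pseudo-random.
#' @param step marching step along each line, voxels.
#' @param directions optional explicit matrix of unit directions (3 columns,
#'   x/y/z); overrides `n_directions`/`method`.
#' @param dither dither the line-grid origin per direction (seeded);
#'   `FALSE` fixes the grid for reproducible line sets.
#' @return A data.frame of class `mil_set` with columns `dx, dy, dz`
#'   (unit direction, x/y/z components), `mil_mm`, `length_mm`,
#'   `n_intercepts`; attributes record spacing and the dropped-direction
#'   count.
#' @export
sample_mil <- function(vol, n_directions = 5000, line_spacing = 1, seed = 1,
                       method = c("lowdiscrepancy", "random"), step = 0.5,
                       directions = NULL, dither = TRUE) {
  stopifnot(inherits(vol, "binary_volume"))
  if (!any(vol$grid) || all(vol$grid))
    stop("MIL requires both phases present in the volume")
  method <- match.arg(method)
  if (is.null(directions)) {
    if (n_directions < 9) stop("`n_directions` must be >= 9")
    dirs <- hemisphere_directions(n_directions, seed, method)
  } else {
    dirs <- as.matrix(directions)
    stopifnot(ncol(dirs) == 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    n_directions <- nrow(dirs)
  }
  jit <- if (dither)
    with_seed(seed + 1L, matrix(runif(2 * n_directions), ncol = 2))
  else matrix(0, n_directions, 2)
  raw <- cpp_mil_sample(as.logical(vol$grid), dim(vol$grid), dirs,
                        line_spacing, step, jit)
  vs_mm <- vol$voxel_size_um / 1000
  intercepts <- raw[, 2] / 2
  keep <- intercepts > 0 & raw[, 1] > 0
  n_dropped <- sum(!keep)
  if (sum(keep) < 9)
    stop("fewer than 9 directions with intercepts (", n_dropped,
         " dropped); volume too small or single-phase")
  out <- data.frame(dx = dirs[keep, 1], dy = dirs[keep, 2], dz = dirs[keep, 3],
                    mil_mm = raw[keep, 1] * vs_mm / intercepts[keep],
                    length_mm = raw[keep, 1] * vs_mm,
                    n_intercepts = intercepts[keep])
  class(out) <- c("mil_set", "data.frame")
  attr(out, "line_spacing_voxels") <- line_spacing
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Fit the material anisotropy tensor M
#'
#' Least-squares fit of the MIL ellipsoid: the directional mean intercept
#' lengths of cancellous bone lie on the surface of an ellipsoid, so they are
#' equivalent to a positive definite second-rank tensor `M` satisfying
#' `w' M w = 1 / MIL(w)^2` for every unit direction `w`.
#'
#' @param mil a `mil_set` from [sample_mil()], or any data.frame with
#'   columns `dx, dy, dz, mil_mm` (>= 9 rows spanning 3-D).
#' @return An object of class `anisotropy_tensor`: the symmetric matrix `m`,
#'   `eigenvalues` (ascending, `d1 <= d2 <= d3`) and orthonormal
#'   `eigenvectors` (columns matching the eigenvalues).
#' @export
fit_anisotropy_tensor <- function(mil) {
  if (nrow(mil) < 9) stop("need at least 9 usable directions")
  w <- as.matrix(mil[, c("dx", "dy", "dz")])
  X <- cbind(w[, 1]^2, w[, 2]^2, w[, 3]^2,
             2 * w[, 1] * w[, 2], 2 * w[, 1] * w[, 3], 2 * w[, 2] * w[, 3])
  b <- 1 / mil$mil_mm^2
  beta <- qr.coef(qr(X), b)
  if (any(!is.finite(beta)))
    stop("direction set does not span 3-D; cannot fit a tensor")
  m <- matrix(c(beta[1], beta[4], beta[5],
                beta[4], beta[2], beta[6],
                beta[5], beta[6], beta[3]), 3, 3)
  es <- eigen(m, symmetric = TRUE) # eigenvalues descending
  ord <- 3:1
  ev <- es$values[ord]
  if (ev[1] <= 0)
    stop("fitted tensor is not positive definite; use more directions or a ",
         "larger volume")
  structure(list(m = m, eigenvalues = ev,
                 eigenvectors = es$vectors[, ord, drop = FALSE]),
            class = "anisotropy_tensor")
}

#' @export
print.anisotropy_tensor <- function(x, ...) {
  cat("<anisotropy_tensor> eigenvalues (D1 <= D2 <= D3):",
      sprintf("%.4g", x$eigenvalues), "\n")
  cat("  DA =", sprintf("%.4f", degree_of_anisotropy(x)), "\n")
  invisible(x)
}

#' Degree of anisotropy
#'
#' `DA = 1 - D1/D3` from the ascending eigenvalues of the material
#' anisotropy tensor: 0 for a completely isotropic volume, approaching 1 for
#' a fully oriented one.
#'
#' @param t an `anisotropy_tensor` (or a list with ascending `eigenvalues`).
#' @return DA in \[0, 1).
#' @export
degree_of_anisotropy <- function(t) {
  ev <- t$eigenvalues
  if (ev[1] <= 0) stop("tensor must be positive definite")
  1 - ev[1] / ev[3]
}

#' Fabric tensor and normalized eigenvalues
#'
#' The fabric tensor is `A = M^(-1/2)`; its eigenvalues (the principal radii
#' of the MIL ellipsoid) are sorted descending (`A11 > A22 > A33`, so the
#' first eigenvector `e1` is the principal trabecular direction) and
#' normalized to `lambda_i = A_ii / (A11 + A22 + A33)`, which sum to one.
#'
#' @param t an `anisotropy_tensor` from [fit_anisotropy_tensor()].
#' @return An object of class `fabric_result`: matrix `a`, `a_eigenvalues`
#'   (descending), `eigenvectors` (columns `e1, e2, e3`), `lambda`, `da`,
#'   `angles_deg` (`alpha, beta, gamma`: angles of `e1` against the x, y and
#'   z axes), and `degenerate` (near-equal eigenvalue flag).
#' @export
fabric_from_anisotropy <- function(t) {
  ev <- t$eigenvalues
  if (ev[1] <= 0) stop("tensor must be positive definite")
  a_vals <- ev^(-0.5) # descending: smallest d -> largest radius
  vecs <- t$eigenvectors # columns match ascending d, i.e. descending a
  degenerate <- any(abs(diff(a_vals)) / a_vals[1] < 1e-6)
  if (degenerate) {
    # tie-break: order near-equal eigenvectors by |e.z|, then |e.y|
    grp <- cumsum(c(TRUE, abs(diff(a_vals)) / a_vals[1] >= 1e-6))
    for (gi in unique(grp)) {
      idx <- which(grp == gi)
      if (length(idx) > 1) {
        key <- order(-abs(vecs[3, idx]), -abs(vecs[2, idx]))
        vecs[, idx] <- vecs[, idx[key]]
        a_vals[idx] <- a_vals[idx[key]]
      }
    }
  }
  a <- vecs %*% diag(a_vals) %*% t(vecs)
  lambda <- a_vals / sum(a_vals)
  e1 <- vecs[, 1]
  clamp <- function(x) pmin(pmax(x, -1), 1)
  angles <- acos(clamp(abs(e1))) * 180 / pi # vs x, y, z axes
  structure(list(a = a, a_eigenvalues = a_vals, eigenvectors = vecs,
                 lambda = lambda, da = degree_of_anisotropy(t),
                 angles_deg = setNames(angles, c("alpha", "beta", "gamma")),
                 degenerate = degenerate),
            class = "fabric_result")
}

#' @export
print.fabric_result <- function(x, ...) {
  cat("<fabric_result>\n")
  cat("  A eigenvalues:", sprintf("%.4g", x$a_eigenvalues), "\n")
  cat("  lambda:", sprintf("%.4f", x$lambda),
      " (sum", format(sum(x$lambda)), ")\n")
  cat(sprintf("  DA = %.4f\n", x$da))
  cat(sprintf("  angles (deg): alpha %.1f, beta %.1f, gamma %.1f\n",
              x$angles_deg[1], x$angles_deg[2], x$angles_deg[3]))
  if (x$degenerate) cat("  note: near-degenerate eigenvalues (tie-break applied)\n")
  invisible(x)
}

#' Orientation angles of the principal trabecular direction
#'
#' Direction cosines of the principal fabric axis `e1` (largest fabric
#' eigenvalue) against the volume axes, folded into \[0, 90\] degrees:
#' `gamma = acos(|e1 . z|)` etc.
#'
#' @param f a `fabric_result`.
#' @return Named numeric vector `(alpha, beta, gamma)`, degrees.
#' @export
orientation_angles <- function(f) {
  stopifnot(inherits(f, "fabric_result"))
  f$angles_deg
}

#' Measure fabric of a volume
#'
#' Convenience composition: [sample_mil()], [fit_anisotropy_tensor()],
#' [fabric_from_anisotropy()].
#'
#' @inheritParams sample_mil
#' @return A `fabric_result` with the `anisotropy_tensor` attached as
#'   attribute `"tensor"` and the MIL set as `"mil"`.
#' @export
measure_fabric <- function(vol, n_directions = 5000, line_spacing = 1,
                           seed = 1, method = c("lowdiscrepancy", "random"),
                           step = 0.5) {
  mil <- sample_mil(vol, n_directions, line_spacing, seed, method, step)
  t <- fit_anisotropy_tensor(mil)
  f <- fabric_from_anisotropy(t)
  attr(f, "tensor") <- t
  attr(f, "mil") <- mil
  f
}
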