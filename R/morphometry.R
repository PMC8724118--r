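#' Bone volume fraction (BV/TV)
#'
#' Foreground (bone) voxels over total voxels.
#'
#' @param vol a [binary_volume()].
#' @return A single number in \[0, 1\].
#' @export
bone_volume_fraction <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  sum(vol$grid) / length(vol$grid)
}

#' Bone surface density (BS/TV)
#'
#' Triangulates the bone/marrow interface at iso-level 0.5 (marching
#' tetrahedra on a lightly Gaussian-smoothed copy of the binary grid; the
#' light smoothing removes the voxelization staircase that would otherwise
#' bias the area upward by ~9\%) and divides the mesh area by the total
#' volume.  Faces where the structure is clipped by the volume boundary are
#' excluded (open-boundary policy, appropriate for interior VOIs); set
#' `closed_boundary = TRUE` to cap clipped structures instead.
#'
#' @param vol a [binary_volume()].
#' @param smooth_sigma pre-smoothing SD in voxels (0 disables smoothing).
#' @param closed_boundary close the surface at the volume boundary.
#' @return BS/TV in 1/mm; 0 (with a warning) for an empty foreground.
#' @export
bone_surface_density <- function(vol, smooth_sigma = 0.8,
                                 closed_boundary = FALSE) {
  stopifnot(inherits(vol, "binary_volume"))
  if (!any(vol$grid)) {
    warning("empty foreground: BS/TV = 0")
    return(0)
  }
  field <- array(as.numeric(vol$grid), dim(vol$grid))
  if (closed_boundary) {
    d0 <- dim(field)
    padded <- array(0, d0 + 2L)
    padded[2:(d0[1] + 1), 2:(d0[2] + 1), 2:(d0[3] + 1)] <- field
    field <- padded
  }
  if (smooth_sigma > 0) field <- smooth_gaussian(field, smooth_sigma)
  area_vox2 <- cpp_mt_area(as.numeric(field), dim(field), 0.5)
  vs_mm <- vol$voxel_size_um / 1000
  tv_mm3 <- prod(dim(vol$grid)) * vs_mm^3
  area_vox2 * vs_mm^2 / tv_mm3
}

#' Local thickness map (Tb.Th. / Tb.Sp.)
#'
#' Hildebrand-Rueegsegger model-independent thickness: the thickness at a
#' point is the diameter of the largest sphere that fits entirely inside the
#' phase and contains the point (Euclidean distance transform, distance
#' ridge, sphere painting).  Run on the foreground it yields trabecular
#' thickness (Tb.Th.); on the background, trabecular separation (Tb.Sp.).
#'
#' @param vol a [binary_volume()].
#' @param phase `"foreground"` (bone) or `"background"` (marrow).
#' @return A list with `map` (3-D array of local thickness in micrometres, 0
#'   outside the phase) and `stats` (a [describe_stats()] summary over the
#'   phase voxels, micrometres).
#' @export
local_thickness <- function(vol, phase = c("foreground", "background")) {
  stopifnot(inherits(vol, "binary_volume"))
  phase <- match.arg(phase)
  fg <- phase == "foreground"
  sel <- if (fg) vol$grid else !vol$grid
  if (!any(sel)) stop("selected phase is empty")
  if (all(sel))
    stop("opposite phase is empty: local thickness is unbounded")
  th <- cpp_local_thickness(as.logical(vol$grid), dim(vol$grid), fg)
  map <- array(th * vol$voxel_size_um, dim(vol$grid))
  list(map = map, stats = describe_stats(map[sel]))
}

# Euler characteristic of the foreground cubical complex (union of closed
# unit voxels; matches 26-connectivity of the foreground):
# chi = V - E + F - C over vertices, edges, faces, cells.
euler_characteristic <- function(grid) {
  d <- dim(grid)
  P <- array(FALSE, d + 2L)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- grid
  win <- function(dz, dy, dx, len) # shifted window of P with given extent
    P[dz + seq_len(len[1]), dy + seq_len(len[2]), dx + seq_len(len[3])]
  count_or <- function(shifts, len) {
    acc <- array(FALSE, len)
    for (s in shifts) acc <- acc | win(s[1], s[2], s[3], len)
    sum(acc)
  }
  b <- c(0L, 1L)
  V <- count_or(expand_shifts(b, b, b), d + 1L)
  Ez <- count_or(expand_shifts(2L, b, b), c(d[1], d[2] + 1L, d[3] + 1L))
  Ey <- count_or(expand_shifts(b, 2L, b), c(d[1] + 1L, d[2], d[3] + 1L))
  Ex <- count_or(expand_shifts(b, b, 2L), c(d[1] + 1L, d[2] + 1L, d[3]))
  Fz <- count_or(expand_shifts(b, 2L, 2L), c(d[1] + 1L, d[2], d[3]))
  Fy <- count_or(expand_shifts(2L, b, 2L), c(d[1], d[2] + 1L, d[3]))
  Fx <- count_or(expand_shifts(2L, 2L, b), c(d[1], d[2], d[3] + 1L))
  C <- sum(grid)
  V - (Ez + Ey + Ex) + (Fz + Fy + Fx) - C
}

# All (dz, dy, dx) shift triples; an entry of 2 means "fixed interior offset"
# (the window excludes the pad on that axis and spans the cell extent).
expand_shifts <- function(z, y, x) {
  z <- if (identical(z, 2L)) 1L else z
  y <- if (identical(y, 2L)) 1L else y
  x <- if (identical(x, 2L)) 1L else x
  g <- expand.grid(dz = z, dy = y, dx = x)
  lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
}

#' Connectivity density (Conn.D.)
#'
#' First Betti number of the trabecular network per unit volume, computed
#' from the Euler characteristic of the foreground cubical complex as
#' `Conn.D = (1 - chi) / TV`, assuming one connected component and no
#' enclosed cavities.  Negative values are possible for multi-component
#' inputs and are reported as computed; the component count is attached as a
#' diagnostic.
#'
#' @param vol a [binary_volume()].
#' @return Conn.D. in 1/mm^3, with attributes `"euler"` and
#'   `"n_components"`.
#' @export
connectivity_density <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  if (!any(vol$grid)) stop("empty foreground")
  chi <- euler_characteristic(vol$grid)
  lab <- cpp_label26(as.logical(vol$grid), dim(vol$grid))
  vs_mm <- vol$voxel_size_um / 1000
  tv <- prod(dim(vol$grid)) * vs_mm^3
  out <- (1 - chi) / tv
  attr(out, "euler") <- chi
  attr(out, "n_components") <- attr(lab, "n_components")
  out
}

#' Ellipsoid factor value
#'
#' `EF = a/b - b/c` for semi-axes `a <= b <= c`: -1 for an ideal plate
#' (oblate), +1 for an ideal rod (prolate), 0 for a sphere (`a = b = c`).
#'
#' @param a,b,c semi-axes, sorted ascending.
#' @return A number in \[-1, 1\].
#' @export
ef_value <- function(a, b, c) {
  if (any(c(a, b, c) <= 0)) stop("semi-axes must be positive")
  if (a > b || b > c) stop("semi-axes must satisfy a <= b <= c")
  a / b - b / c
}

#' Ellipsoid factor (EF) of the trabecular phase
#'
#' At seed points sampled on the medial skeleton (distance-ridge voxels), a
#' maximal inscribed ellipsoid is grown: starting from the maximal inscribed
#' sphere (radius from the Euclidean distance transform), each semi-axis is
#' dilated greedily along several candidate orthonormal triads (the grid
#' triad plus seeded random rotations) while the in-volume part of the
#' ellipsoid surface stays inside the phase (points beyond the VOI boundary
#' do not veto growth); the largest-volume ellipsoid wins and contributes
#' `EF = a/b - b/c`.
#'
#' @param vol a [binary_volume()].
#' @param n_seeds number of skeleton seed points (>= 1).
#' @param seed RNG seed for seed-point and orientation sampling.
#' @param n_orientations candidate triads per seed (first is axis-aligned).
#' @param max_iter dilation iterations per triad.
#' @param step semi-axis increment per accepted dilation, voxels.
#' @param n_surface surface sample points for the containment test.
#' @return A list with `ef` (per-seed values) and `stats`
#'   (a [describe_stats()] summary).
#' @export
ellipsoid_factor <- function(vol, n_seeds = 100, seed = 1,
                             n_orientations = 8, max_iter = 100, step = 0.5,
                             n_surface = 150) {
  stopifnot(inherits(vol, "binary_volume"))
  if (n_seeds < 1) stop("`n_seeds` must be >= 1")
  g <- vol$grid
  d <- dim(g)
  if (!any(g)) stop("empty foreground")
  if (all(g)) stop("opposite phase is empty: no inscribed ellipsoids exist")
  ed2 <- array(cpp_edt_sq(as.logical(g), d, TRUE), d)
  if (max(ed2) <= 1) {
    warning("structure everywhere thinner than 1 voxel: EF from unit spheres")
    return(list(ef = 0, stats = describe_stats(0)))
  }
  # medial-skeleton candidates: local maxima of the squared EDT (26-nhd)
  is_max <- g & ed2 > 0
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (!dz && !dy && !dx) next
    sh <- array(0, d)
    zi <- pmin(pmax(seq_len(d[1]) + dz, 1L), d[1])
    yi <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    xi <- pmin(pmax(seq_len(d[3]) + dx, 1L), d[3])
    is_max <- is_max & ed2 >= ed2[zi, yi, xi]
  }
  cand <- which(is_max)
  if (!length(cand)) cand <- which(g & ed2 == max(ed2))
  picks <- with_seed(seed, cand[sample.int(length(cand),
                                           min(n_seeds, length(cand)))])
  triads <- with_seed(seed + 1L, c(list(diag(3)),
    lapply(seq_len(max(0, n_orientations - 1)), function(i) random_rotation())))
  usph <- sphere_points(n_surface)
  # containment is judged on the in-volume part of the ellipsoid surface:
  # points beyond the VOI boundary do not veto growth (open-boundary policy,
  # consistent with structures continuing outside an interior VOI)
  inside <- function(pts) { # pts: n x 3 (x, y, z), voxel coords
    iz <- floor(pts[, 3]) + 1L; iy <- floor(pts[, 2]) + 1L; ix <- floor(pts[, 1]) + 1L
    ok <- iz >= 1 & iy >= 1 & ix >= 1 & iz <= d[1] & iy <= d[2] & ix <= d[3]
    all(g[cbind(iz[ok], iy[ok], ix[ok])])
  }
  efs <- vapply(picks, function(i) {
    ijk <- arrayInd(i, d) # (z, y, x), 1-based
    ctr <- c(ijk[3], ijk[2], ijk[1]) - 0.5 # (x, y, z)
    # shrink by a full voxel: membership is tested voxel-wise, so a surface
    # point can land in a background voxel up to ~sqrt(3)/2 beyond the EDT
    r0 <- max(sqrt(ed2[i]) - 1, 0.5)
    best <- c(r0, r0, r0); best_vol <- prod(best)
    for (R in triads) {
      semi <- c(r0, r0, r0)
      frozen <- c(FALSE, FALSE, FALSE)
      for (it in seq_len(max_iter)) {
        k <- (it - 1) %% 3 + 1
        if (frozen[k]) { if (all(frozen)) break else next }
        trial <- semi; trial[k] <- trial[k] + step
        pts <- sweep(usph %*% diag(trial) %*% t(R), 2, ctr, "+")
        if (inside(pts)) semi <- trial else frozen[k] <- TRUE
        if (all(frozen)) break
      }
      if (prod(semi) > best_vol) { best <- semi; best_vol <- prod(semi) }
    }
    s <- sort(best)
    ef_value(s[1], s[2], s[3])
  }, numeric(1))
  list(ef = efs, stats = describe_stats(efs))
}

#' Surface-fraction model BS/TV = K * BV/TV * (1 - BV/TV)
#'
#' The simplest one-parameter relation satisfying the physical constraints
#' that bone with no volume and bone with no pores both have no surface.
#'
#' @param bv_tv bone volume fraction(s) in \[0, 1\].
#' @param K model constant (1/mm).
#' @return Predicted BS/TV (1/mm), same length as `bv_tv`.
#' @export
surface_model_predict <- function(bv_tv, K) {
  if (any(bv_tv < 0 | bv_tv > 1)) stop("`bv_tv` must lie in [0, 1]")
  K * bv_tv * (1 - bv_tv)
}

#' Morphometric profile of a volume
#'
#' Convenience wrapper computing all morphological indices of a sample.
#'
#' @param vol a [binary_volume()].
#' @param ef_seeds seed points for [ellipsoid_factor()]; 0 skips EF.
#' @param thickness compute Tb.Th./Tb.Sp. maps (the costliest step).
#' @param seed RNG seed for EF sampling.
#' @return A list of class `morphometry_result`.
#' @export
morphometry <- function(vol, ef_seeds = 100, thickness = TRUE, seed = 1) {
  stopifnot(inherits(vol, "binary_volume"))
  res <- list(
    bv_tv = bone_volume_fraction(vol),
    bs_tv = bone_surface_density(vol),
    conn_d = as.numeric(connectivity_density(vol)))
  if (thickness) {
    res$tb_th_um <- local_thickness(vol, "foreground")$stats
    res$tb_sp_um <- local_thickness(vol, "background")$stats
  }
  if (ef_seeds > 0)
    res$ef <- ellipsoid_factor(vol, n_seeds = ef_seeds, seed = seed)$stats
  structure(res, class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("<morphometry_result>\n")
  cat(sprintf("  BV/TV  = %.4f\n", x$bv_tv))
  cat(sprintf("  BS/TV  = %.3f 1/mm\n", x$bs_tv))
  cat(sprintf("  Conn.D = %.3f 1/mm^3\n", x$conn_d))
  if (!is.null(x$tb_th_um))
    cat(sprintf("  Tb.Th  = %.1f um (SD %.1f)\n", x$tb_th_um$mean, x$tb_th_um$sd))
  if (!is.null(x$tb_sp_um))
    cat(sprintf("  Tb.Sp  = %.1f um (SD %.1f)\n", x$tb_sp_um$mean, x$tb_sp_um$sd))
  if (!is.null(x$ef))
    cat(sprintf("  EF     = %.3f (SD %.3f)\n", x$ef$mean, x$ef$sd))
  invisible(x)
}
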