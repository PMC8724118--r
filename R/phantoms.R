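#' Generate a synthetic binary phantom
#'
#' Seeded generators producing [binary_volume()] objects with known ground
#' truth, for validating every downstream stage without real micro-CT data.
#'
#' Kinds:
#' \describe{
#'   \item{`sphere`}{solid ball of `radius` voxels, centred.}
#'   \item{`slab`}{solid slab of `thickness` voxels spanning the volume,
#'     normal to `axis`.}
#'   \item{`rod_lattice`}{`n_nodes^3` lattice of axis-aligned square rods of
#'     half-width `rod_radius`, node spacing `spacing` voxels; its first
#'     Betti number is `3*n^2*(n-1) - n^3 + 1`.}
#'   \item{`parallel_plates`}{periodic plates of `thickness` voxels with
#'     period `period`, normal to `axis`; BV/TV = thickness/period exactly
#'     when the extent is a multiple of the period.}
#'   \item{`grf_trabecular`}{oriented trabecular emulator: seeded white
#'     noise smoothed with an anisotropic Gaussian kernel (per-axis sigmas
#'     `sigma * stretch`, first local axis rotated onto `direction`),
#'     thresholded at the `1 - bvtv` quantile of the smoothed field so the
#'     achieved volume fraction matches the target to within one voxel
#'     count.  One stretched axis gives rod-like, two give plate-like
#'     structure.}
#' }
#'
#' @param kind phantom type, see Details.
#' @param shape voxels per axis; scalar or `(nz, ny, nx)` triple.
#' @param voxel_size_um voxel edge length in micrometres.
#' @param radius sphere radius in voxels.
#' @param thickness slab/plate thickness in voxels.
#' @param axis slab/plate normal, `"z"`, `"y"` or `"x"`.
#' @param period plate repeat distance in voxels.
#' @param n_nodes,rod_radius,spacing rod-lattice geometry (nodes per axis,
#'   rod half-width, node spacing in voxels).
#' @param bvtv target bone volume fraction, strictly in (0, 1)
#'   (`grf_trabecular`).
#' @param direction principal trabecular orientation, unit 3-vector
#'   `(x, y, z)` (`grf_trabecular`).
#' @param stretch per-axis anisotropy stretch ratios (>= 1), first entry
#'   along `direction`.
#' @param sigma base smoothing length in voxels; sets the trabecular scale.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return A [binary_volume()]; for `grf_trabecular` the attribute
#'   `"ground_truth"` stores the target parameters.
#' @examples
#' v <- make_phantom("sphere", shape = 32, radius = 10)
#' bone_volume_fraction(v)
#' @export
make_phantom <- function(kind = c("sphere", "slab", "rod_lattice",
                                  "parallel_plates", "grf_trabecular"),
                         shape = 64, voxel_size_um = 80,
                         radius = NULL, thickness = NULL, axis = "z",
                         period = NULL, n_nodes = NULL, rod_radius = 1,
                         spacing = NULL, bvtv = NULL,
                         direction = c(0, 0, 1), stretch = c(1, 1, 1),
                         sigma = 2.5, seed = 1) {
  kind <- match.arg(kind)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  if (any(shape < 2L)) stop("degenerate shape: every axis must be >= 2")
  d <- shape # (nz, ny, nx)
  ax <- match(match.arg(axis, c("z", "y", "x")), c("z", "y", "x"))

  grid <- switch(kind,
    sphere = {
      if (is.null(radius) || radius <= 0) stop("sphere needs a positive `radius`")
      if (2 * radius > min(d)) stop("sphere of radius ", radius,
                                    " does not fit inside the volume")
      ctr <- (d - 1) / 2
      z <- slice.index(array(0, d), 1) - 1 - ctr[1]
      y <- slice.index(array(0, d), 2) - 1 - ctr[2]
      x <- slice.index(array(0, d), 3) - 1 - ctr[3]
      array(z^2 + y^2 + x^2 <= radius^2, d)
    },
    slab = {
      if (is.null(thickness) || thickness < 1) stop("slab needs `thickness` >= 1")
      if (thickness > d[ax]) stop("slab thicker than the volume")
      start <- (d[ax] - thickness) %/% 2 + 1L
      idx <- slice.index(array(0, d), ax)
      array(idx >= start & idx < start + thickness, d)
    },
    parallel_plates = {
      if (is.null(thickness) || is.null(period) || thickness < 1 ||
          period <= thickness)
        stop("parallel_plates needs `thickness` >= 1 and `period` > thickness")
      idx <- slice.index(array(0, d), ax)
      array(((idx - 1L) %% period) < thickness, d)
    },
    rod_lattice = {
      if (is.null(n_nodes) || n_nodes < 2) stop("rod_lattice needs `n_nodes` >= 2")
      spacing <- spacing %||% max(4L, (min(d) - 2L * rod_radius - 2L) %/% (n_nodes - 1L))
      span <- (n_nodes - 1L) * spacing
      if (span + 2 * rod_radius + 2 > min(d))
        stop("rod lattice does not fit: span ", span, " + rods exceeds volume")
      off <- (d - span) / 2
      nodes <- lapply(1:3, function(a) off[a] + (0:(n_nodes - 1L)) * spacing)
      near <- function(a) {
        ix <- slice.index(array(0, d), a) - 1
        res <- array(FALSE, d)
        for (p in nodes[[a]]) res <- res | abs(ix - p) <= rod_radius
        res
      }
      within <- function(a) {
        ix <- slice.index(array(0, d), a) - 1
        ix >= nodes[[a]][1] - rod_radius & ix <= nodes[[a]][n_nodes] + rod_radius
      }
      nz <- near(1); ny <- near(2); nx <- near(3)
      (within(1) & ny & nx) | (nz & within(2) & nx) | (nz & ny & within(3))
    },
    grf_trabecular = {
      if (any(d < 16L)) stop("grf_trabecular needs at least 16 voxels per axis")
      if (is.null(bvtv) || bvtv <= 0 || bvtv >= 1)
        stop("grf_trabecular needs target `bvtv` strictly in (0, 1)")
      if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
        stop("`direction` must be a unit vector")
      if (any(stretch < 1)) stop("`stretch` ratios must be >= 1")
      field <- grf_field(d, sigma, direction, stretch, seed)
      k <- max(1L, round(bvtv * prod(d)))
      thr <- sort(field, decreasing = TRUE)[k]
      array(field >= thr, d)
    })

  out <- binary_volume(grid, voxel_size_um)
  if (kind == "grf_trabecular")
    attr(out, "ground_truth") <- list(kind = kind, bvtv = bvtv,
                                      direction = direction, stretch = stretch,
                                      sigma = sigma, seed = seed)
  out
}

# Stationary anisotropic Gaussian random field: white noise filtered in the
# Fourier domain by a Gaussian transfer function with covariance
# R diag((sigma*stretch)^2) R^T, R rotating the first local axis onto
# `direction`.  Periodic boundary keeps the field stationary.
grf_field <- function(d, sigma, direction, stretch, seed) {
  noise <- with_seed(seed, array(rnorm(prod(d)), d))
  sig <- sigma * stretch
  # local frame: axis 1 along direction (x, y, z)
  R <- rotation_z_to(direction)
  R <- R[, c(3, 1, 2)] # columns: direction, two orthogonal completions
  Sigma <- R %*% diag(sig^2) %*% t(R) # in (x, y, z)
  freq <- function(n) { k <- 0:(n - 1); ifelse(k > n / 2, k - n, k) / n }
  fz <- freq(d[1]); fy <- freq(d[2]); fx <- freq(d[3])
  KZ <- array(rep(fz, times = d[2] * d[3]), d)
  KY <- array(rep(rep(fy, each = d[1]), times = d[3]), d)
  KX <- array(rep(fx, each = d[1] * d[2]), d)
  # quadratic form k' Sigma k with k = (kx, ky, kz)
  q <- Sigma[1, 1] * KX^2 + Sigma[2, 2] * KY^2 + Sigma[3, 3] * KZ^2 +
    2 * (Sigma[1, 2] * KX * KY + Sigma[1, 3] * KX * KZ + Sigma[2, 3] * KY * KZ)
  transfer <- exp(-2 * pi^2 * q)
  Re(fft(fft(noise) * transfer, inverse = TRUE)) / prod(d)
}

#' Generate a synthetic cohort of trabecular volumes
#'
#' Emulates a multi-sample study: `n` oriented `grf_trabecular` phantoms whose
#' target volume fractions span `bvtv_range`, with the principal direction
#' jittered around the z-axis and per-sample anisotropy stretch.  Each sample
#' carries cyclic vertebral-level (`L1`..`L5`) and region
#' (`ac`/`pc`/`pl`/`pr`) tags so grouped summaries can be exercised.
#'
#' @param n number of samples (>= 1).
#' @param bvtv_range interval of target volume fractions, inside (0, 1).
#' @param orientation_jitter_deg SD of the angular jitter of the principal
#'   direction about the z-axis, in degrees.
#' @param seed integer seed; the cohort is bit-reproducible given the seed.
#' @param shape voxels per axis for every sample.
#' @param voxel_size_um voxel size in micrometres.
#' @param stretch_range range of the principal-axis stretch ratio.
#' @return A list with one element per sample: `volume` (a
#'   [binary_volume()]) and `truth` (target BV/TV, direction, stretch, seed).
#' @export
make_cohort <- function(n, bvtv_range = c(0.082, 0.194),
                        orientation_jitter_deg = 8, seed = 1,
                        shape = 64, voxel_size_um = 80,
                        stretch_range = c(1.6, 2.4)) {
  if (n < 1) stop("`n` must be >= 1")
  if (length(bvtv_range) != 2L || bvtv_range[1] >= bvtv_range[2] ||
      bvtv_range[1] <= 0 || bvtv_range[2] >= 1)
    stop("`bvtv_range` must be a non-empty interval inside (0, 1)")
  targets <- if (n == 1) mean(bvtv_range) else
    seq(bvtv_range[1], bvtv_range[2], length.out = n)
  pars <- with_seed(seed, {
    ang <- abs(rnorm(n, 0, orientation_jitter_deg)) * pi / 180
    az <- runif(n, 0, 2 * pi)
    s <- runif(n, stretch_range[1], stretch_range[2])
    ord <- sample.int(n) # decouple bvtv from tag order
    list(ang = ang, az = az, s = s, ord = ord)
  })
  levels <- paste0("L", 1:5)
  regions <- c("ac", "pc", "pl", "pr")
  lapply(seq_len(n), function(i) {
    dvec <- c(sin(pars$ang[i]) * cos(pars$az[i]),
              sin(pars$ang[i]) * sin(pars$az[i]),
              cos(pars$ang[i]))
    dvec <- dvec / sqrt(sum(dvec^2))
    seed_i <- as.integer((as.numeric(seed) * 1009 + i) %% 2147483629)
    vol <- make_phantom("grf_trabecular", shape = shape,
                        voxel_size_um = voxel_size_um,
                        bvtv = targets[pars$ord[i]],
                        direction = dvec, stretch = c(pars$s[i], 1, 1),
                        seed = seed_i)
    vol$label <- sprintf("S%03d", i)
    vol$level <- levels[((i - 1) %/% 4) %% 5 + 1]
    vol$region <- regions[(i - 1) %% 4 + 1]
    list(volume = vol,
         truth = list(bvtv = targets[pars$ord[i]], direction = dvec,
                      stretch = c(pars$s[i], 1, 1), seed = seed_i))
  })
}
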