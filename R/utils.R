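# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Normalized Gaussian kernel truncated at 3 sigma (odd length >= 3).
gaussian_kernel <- function(sigma) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-h, h)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 3-D numeric array, clamp-to-edge padding.
smooth_gaussian <- function(arr, sigma) {
  d <- dim(arr)
  k <- gaussian_kernel(sigma)
  out <- as.numeric(arr)
  for (axis in 0:2) out <- cpp_sep_convolve(out, d, k, axis)
  array(out, d)
}

# Uniformly-distributed unit vectors on the upper hemisphere.
# Low-discrepancy: spherical Fibonacci lattice, de-aligned from the grid axes
# by a seeded random rotation.  Random: i.i.d. uniform on the hemisphere.
hemisphere_directions <- function(n, seed, method = c("lowdiscrepancy", "random")) {
  method <- match.arg(method)
  if (method == "lowdiscrepancy") {
    i <- seq_len(n) - 0.5
    z <- i / n
    phi <- 2 * pi * i * (sqrt(5) - 1) / 2
    r <- sqrt(pmax(0, 1 - z^2))
    dirs <- cbind(r * cos(phi), r * sin(phi), z)
    rot <- with_seed(seed, random_rotation())
    dirs <- dirs %*% t(rot)
    # fold into the upper hemisphere (antipodal equivalence for MIL)
    flip <- dirs[, 3] < 0
    dirs[flip, ] <- -dirs[flip, ]
    dirs
  } else {
    with_seed(seed, {
      z <- runif(n)
      phi <- runif(n, 0, 2 * pi)
      r <- sqrt(pmax(0, 1 - z^2))
      cbind(r * cos(phi), r * sin(phi), z)
    })
  }
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# Rotation taking the z-axis onto unit vector `d`.
rotation_z_to <- function(d) {
  d <- d / sqrt(sum(d^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * d[3] - z[3] * d[2], z[3] * d[1] - z[1] * d[3], z[1] * d[2] - z[2] * d[1])
  c_ <- sum(z * d)
  if (abs(c_ + 1) < 1e-12) return(diag(c(1, -1, -1)))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# Fibonacci lattice on the full unit sphere (deterministic).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
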