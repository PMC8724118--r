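# Independent oracles used across the suite.  Each re-derives a quantity by
# a different route than the implementation under test.

# Brute-force MIL line walk: same line parameterization as the sampler
# (parallel grid perpendicular to each direction, samples at integer
# multiples of `step` along the ray), but implemented as a naive full-range
# walk in R with per-sample bounds tests — no analytic ray clipping.
# Returns per-direction total in-volume length and boundary crossings.
mil_walk_oracle <- function(vol, dirs, spacing = 1, step = 0.5) {
  g <- vol$grid
  d <- dim(g) # (nz, ny, nx)
  ctr <- c(d[3], d[2], d[1]) / 2 # (x, y, z)
  R <- 0.5 * sqrt(sum(d^2)) + 1
  out <- matrix(0, nrow(dirs), 2)
  for (di in seq_len(nrow(dirs))) {
    w <- dirs[di, ]
    ax <- which.min(abs(w))
    a3 <- c(0, 0, 0); a3[ax] <- 1
    u <- c(w[2] * a3[3] - w[3] * a3[2], w[3] * a3[1] - w[1] * a3[3],
           w[1] * a3[2] - w[2] * a3[1])
    u <- u / sqrt(sum(u^2))
    v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
           w[1] * u[2] - w[2] * u[1])
    tvals <- (ceiling(-R / step):floor(R / step)) * step
    crossings <- 0; inside <- 0
    a <- -R
    while (a <= R) {
      b <- -R
      while (b <= R) {
        o <- ctr + a * u + b * v
        px <- o[1] + tvals * w[1]
        py <- o[2] + tvals * w[2]
        pz <- o[3] + tvals * w[3]
        ix <- floor(px); iy <- floor(py); iz <- floor(pz)
        ok <- ix >= 0 & iy >= 0 & iz >= 0 & ix < d[3] & iy < d[2] & iz < d[1]
        vals <- rep(-1L, length(tvals))
        if (any(ok))
          vals[ok] <- as.integer(g[cbind(iz[ok] + 1L, iy[ok] + 1L, ix[ok] + 1L)])
        inside <- inside + sum(ok)
        # same persistence rule as the sampler: a phase change counts only
        # once the new phase holds for two consecutive samples
        conf <- -1L; cand <- -1L
        for (vv in vals) {
          if (vv < 0L) { conf <- -1L; cand <- -1L; next }
          if (conf < 0L) {
            if (cand == vv) conf <- vv else cand <- vv
          } else if (vv != conf) {
            if (cand == vv) { crossings <- crossings + 1; conf <- vv; cand <- -1L }
            else cand <- vv
          } else cand <- -1L
        }
        b <- b + spacing
      }
      a <- a + spacing
    }
    out[di, ] <- c(inside * step, crossings)
  }
  out
}

# Term-by-term transcription of the orthotropic fabric-elasticity relations,
# written independently of the package implementation (explicit index
# bookkeeping, no loops shared with the package code).
eq8_transcription_oracle <- function(lambda, bvtv, constants) {
  k <- constants$k_a + constants$k_b * bvtv^constants$p
  l1 <- lambda[1]; l2 <- lambda[2]; l3 <- lambda[3]
  II <- l1 * l2 + l1 * l3 + l2 * l3
  ciiii <- function(li) k[1] + 2 * k[6] + (k[2] + 2 * k[7]) * II +
    2 * (k[3] + 2 * k[8]) * li + (2 * k[4] + k[5] + 4 * k[9]) * li^2
  ciijj <- function(li, lj) k[1] + k[2] * II + k[3] * (li + lj) +
    k[4] * (li^2 + lj^2) + k[5] * li * lj
  cijij <- function(li, lj) k[6] + k[7] * II + k[8] * (li + lj) +
    k[9] * (li^2 + lj^2)
  C <- matrix(0, 6, 6)
  C[1, 1] <- ciiii(l1); C[2, 2] <- ciiii(l2); C[3, 3] <- ciiii(l3)
  C[1, 2] <- C[2, 1] <- ciijj(l1, l2)
  C[1, 3] <- C[3, 1] <- ciijj(l1, l3)
  C[2, 3] <- C[3, 2] <- ciijj(l2, l3)
  C[4, 4] <- cijij(l2, l3)
  C[5, 5] <- cijij(l1, l3)
  C[6, 6] <- cijij(l1, l2)
  C
}

# Closed-form isotropic stiffness (Voigt, engineering shear) from (E, nu).
isotropic_voigt <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

# Wrap a bare Voigt stiffness as an orthotropic_elasticity object.
as_elasticity <- function(C, Et_GPa = 15) {
  structure(list(c_voigt = C, c_voigt_gpa = C * Et_GPa,
                 constants = list(Et_GPa = Et_GPa),
                 eigenvalues = eigen(C, symmetric = TRUE,
                                     only.values = TRUE)$values,
                 valid = all(eigen(C, symmetric = TRUE,
                                   only.values = TRUE)$values > 0)),
            class = "orthotropic_elasticity")
}

# Independent isodata fixed-point iteration over an integer histogram.
isodata_oracle <- function(values) {
  t_old <- -Inf
  t <- mean(range(values))
  while (abs(t - t_old) >= 0.5) {
    t_old <- t
    t <- (mean(values[values <= t_old]) + mean(values[values > t_old])) / 2
  }
  t
}

# Small deterministic grf phantom shared by several tests.
std_phantom <- function(shape = 48, bvtv = 0.15, stretch = c(2, 1, 1),
                        seed = 5)
  make_phantom("grf_trabecular", shape = shape, bvtv = bvtv,
               direction = c(0, 0, 1), stretch = stretch, seed = seed)
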