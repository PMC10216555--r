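#' Deterministic direction sets on the unit sphere
#'
#' `sphereDirections()` returns `n` approximately uniform unit vectors from
#' the Fibonacci (golden-angle) spiral, the deterministic scheme used both
#' for synthetic gradient tables and for numerical spherical averaging of
#' directional kurtosis. `perpendicularDirections()` returns `n` equispaced
#' unit vectors in the plane perpendicular to `axis`, used for radial
#' kurtosis.
#'
#' @param n Number of directions.
#' @param axis Unit 3-vector normal to the requested circle.
#' @return An `n x 3` matrix of unit row vectors.
#' @examples
#' d <- sphereDirections(250)
#' range(sqrt(rowSums(d^2)))  # all 1
#' @export
sphereDirections <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' @rdname sphereDirections
#' @param nIter Iterations of deterministic electrostatic-repulsion
#'   refinement (antipodally symmetric Coulomb energy); 0 returns the raw
#'   spiral.
#' @export
repulsionDirections <- function(n, nIter = 80L, jitter = 0.05) {
  p <- sphereDirections(n)
  if (jitter > 0) {
    # fixed-seed LCG jitter (independent of R's RNG) breaks the spiral's
    # near-symmetries, which can make the quartic design rank-deficient
    p <- p + jitter * matrix(lcgUniform(3L * n) - 0.5, n, 3)
    p <- p / sqrt(rowSums(p^2))
  }
  step <- 0.05 / n
  for (it in seq_len(nIter)) {
    grad <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d <- sweep(p[-i, , drop = FALSE], 2L, p[i, ])
      # antipodal pairs interact too: directions, not orientations
      dA <- sweep(-p[-i, , drop = FALSE], 2L, p[i, ])
      r3 <- (rowSums(d^2) + 1e-12)^1.5
      r3A <- (rowSums(dA^2) + 1e-12)^1.5
      grad[i, ] <- -colSums(d / r3) - colSums(dA / r3A)
    }
    p <- p + step * grad
    p <- p / sqrt(rowSums(p^2))
  }
  p
}

# Spherical quadrature: Gauss-Legendre nodes in the polar cosine crossed
# with uniform azimuth; weights sum to 1. Near-exact for the smooth
# directional-kurtosis integrand at ~250 nodes.
sphereQuadrature <- function(nTheta = 12L, nPhi = 21L) {
  gl <- gaussLegendreRule(nTheta)
  phi <- 2 * pi * (seq_len(nPhi) - 0.5) / nPhi
  z <- rep(gl$nodes, each = nPhi)
  r <- sqrt(pmax(0, 1 - z^2))
  ph <- rep(phi, nTheta)
  list(dirs = cbind(r * cos(ph), r * sin(ph), z),
       weights = rep(gl$weights / 2, each = nPhi) / nPhi)
}

# Minimal linear-congruential stream with a fixed seed; keeps the scheme
# construction deterministic without touching R's global RNG state.
lcgUniform <- function(n, seed = 20260930) {
  m <- 2^31 - 1  # Park-Miller: products stay exact in double precision
  x <- seed %% m
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (16807 * x) %% m
    out[i] <- x / m
  }
  out
}

# Golub-Welsch Gauss-Legendre rule on [-1, 1].
gaussLegendreRule <- function(n) {
  k <- seq_len(n - 1)
  off <- k / sqrt(4 * k^2 - 1)
  j <- diag(0, n)
  j[cbind(k, k + 1)] <- off
  j[cbind(k + 1, k)] <- off
  e <- eigen(j, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
}

#' @rdname sphereDirections
#' @export
perpendicularDirections <- function(axis, n = 64L) {
  axis <- axis / sqrt(sum(axis^2))
  # pick the coordinate axis least aligned with `axis` to seed the basis
  seed <- diag(3)[, which.min(abs(axis))]
  u <- seed - sum(seed * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  theta <- 2 * pi * (seq_len(n) - 1) / n
  outer(cos(theta), u) + outer(sin(theta), v)
}
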