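# Shared fixtures: small deterministic schemes and random-but-seeded
# tensor generators used across the module tests.

smallScheme <- function() makeScheme(15L, c(0, 1000, 2500))

# Random two-compartment tissue parameters on the preset family used by
# the phantom: ideal-cylinder intra-axonal compartment, extra-axonal
# diffusivity dominating axially and radially, random orientation.
randomTissue <- function() {
  v <- stats::rnorm(3)
  v <- v / sqrt(sum(v^2))
  f <- stats::runif(1, 0.1, 0.7)
  daAx <- stats::runif(1, 0.5, 1.5)
  deAx <- daAx + stats::runif(1, 0.3, 1.5)
  deRad <- stats::runif(1, 0.3, min(deAx, daAx + 0.2))
  tissueParams(f = f, daAx = daAx, deAx = deAx, deRad = deRad,
               orientation = v)
}

# Random valid tensor pair (not necessarily two-compartment): positive
# definite D plus a small random symmetric kurtosis tensor.
randomTensorPair <- function(kScale = 0.5) {
  a <- matrix(stats::rnorm(9), 3)
  d <- crossprod(a) / 3 + 0.3 * diag(3)
  md <- sum(diag(d)) / 3
  b <- matrix(stats::rnorm(9), 3)
  w15 <- kScale * gliomaDKI:::w15SymOuter(crossprod(b) / 3) / md^2
  list(d6 = gliomaDKI:::d6FromMatrix(d), w15 = w15, md = md)
}

# Random 3-D rotation matrix (QR of a Gaussian matrix, det +1).
randomRotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Rotate a tensor pair: D -> R D R', W -> rotated order-4 tensor.
rotateTensorPair <- function(tp, rot) {
  d <- rot %*% gliomaDKI:::matrixFromD6(tp$d6) %*% t(rot)
  wIdx <- gliomaDKI:::.w15_idx
  wFull <- array(0, c(3, 3, 3, 3))
  for (k in seq_len(15)) {
    ix <- wIdx[k, ]
    for (pm in unique(asplit(permIndex(ix), 1)))
      wFull[pm[1], pm[2], pm[3], pm[4]] <- tp$w15[k]
  }
  wRot <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- 0
    for (a in 1:3) for (b in 1:3) for (cc in 1:3) for (dd in 1:3)
      s <- s + rot[i, a] * rot[j, b] * rot[k, cc] * rot[l, dd] *
        wFull[a, b, cc, dd]
    wRot[i, j, k, l] <- s
  }
  w15 <- vapply(seq_len(15), function(k) {
    ix <- wIdx[k, ]
    wRot[ix[1], ix[2], ix[3], ix[4]]
  }, numeric(1))
  list(d6 = gliomaDKI:::d6FromMatrix(d), w15 = w15,
       md = sum(diag(d)) / 3)
}

permIndex <- function(ix) {
  perms <- matrix(c(1,2,3,4, 1,2,4,3, 1,3,2,4, 1,3,4,2, 1,4,2,3, 1,4,3,2,
                    2,1,3,4, 2,1,4,3, 2,3,1,4, 2,3,4,1, 2,4,1,3, 2,4,3,1,
                    3,1,2,4, 3,1,4,2, 3,2,1,4, 3,2,4,1, 3,4,1,2, 3,4,2,1,
                    4,1,2,3, 4,1,3,2, 4,2,1,3, 4,2,3,1, 4,3,1,2, 4,3,2,1),
                  ncol = 4, byrow = TRUE)
  t(apply(perms, 1, function(p) ix[p]))
}

# Tiny all-one-zone phantom spec on the given grid.
uniformPhantomSpec <- function(dims, zone = 4L, snr = Inf, seed = 1L,
                               noiseModel = "rician") {
  labels <- array(zone, as.integer(dims))
  phantomSpec(dims = dims, labels = labels, snr = snr, seed = seed,
              noiseModel = noiseModel)
}
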