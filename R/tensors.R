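# Component order conventions used throughout the package.
#
# Diffusion tensor, 6 unique components (units micrometre^2/ms):
#   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), multiplicities (1,1,1,2,2,2).
# Kurtosis tensor W, 15 unique components (dimensionless, MD^2-normalised):
#   (W1111, W2222, W3333, W1112, W1113, W1222, W2223, W1333, W2333,
#    W1122, W1133, W2233, W1123, W1223, W1233),
#   multiplicities (1,1,1,4,4,4,4,4,4,6,6,6,12,12,12).

.d6_idx <- cbind(i = c(1L, 2L, 3L, 1L, 1L, 2L),
                 j = c(1L, 2L, 3L, 2L, 3L, 3L))
.d6_mult <- c(1, 1, 1, 2, 2, 2)

.w15_idx <- matrix(c(1, 1, 1, 1,
                     2, 2, 2, 2,
                     3, 3, 3, 3,
                     1, 1, 1, 2,
                     1, 1, 1, 3,
                     1, 2, 2, 2,
                     2, 2, 2, 3,
                     1, 3, 3, 3,
                     2, 3, 3, 3,
                     1, 1, 2, 2,
                     1, 1, 3, 3,
                     2, 2, 3, 3,
                     1, 1, 2, 3,
                     1, 2, 2, 3,
                     1, 2, 3, 3), ncol = 4, byrow = TRUE)
.w15_mult <- c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)

#' Names of the diffusion-tensor and kurtosis-tensor components
#'
#' Fixed component orders for the 6 unique diffusion-tensor entries and the
#' 15 unique entries of the fully symmetric order-4 kurtosis tensor, as used
#' in every packed representation in this package (design-matrix columns,
#' tensor-field slots, NIfTI tensor volumes).
#'
#' @return Character vector of component labels.
#' @export
dComponentNames <- function() {
  c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
}

#' @rdname dComponentNames
#' @export
wComponentNames <- function() {
  apply(.w15_idx, 1L, function(ix) paste0("W", paste(ix, collapse = "")))
}

# 3x3 symmetric matrix -> packed 6-vector
d6FromMatrix <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

# packed 6-vector -> 3x3 symmetric matrix
matrixFromD6 <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

# Quadratic design row: dot(dQuad(n), d6) == n' D n
dQuad <- function(n) {
  c(n[1]^2, n[2]^2, n[3]^2,
    2 * n[1] * n[2], 2 * n[1] * n[3], 2 * n[2] * n[3])
}

# Quartic design row: dot(wQuart(n), w15) == sum_ijkl n_i n_j n_k n_l W_ijkl
wQuart <- function(n) {
  .w15_mult * apply(.w15_idx, 1L, function(ix) prod(n[ix]))
}

# Rows of dQuad / wQuart for a matrix of directions (n x 3) -> (n x 6), (n x 15)
dQuadRows <- function(dirs) {
  cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
        2 * dirs[, 1] * dirs[, 2],
        2 * dirs[, 1] * dirs[, 3],
        2 * dirs[, 2] * dirs[, 3])
}

wQuartRows <- function(dirs) {
  out <- matrix(0, nrow(dirs), 15L)
  for (k in seq_len(15L)) {
    ix <- .w15_idx[k, ]
    out[, k] <- .w15_mult[k] * dirs[, ix[1]] * dirs[, ix[2]] *
      dirs[, ix[3]] * dirs[, ix[4]]
  }
  out
}

# Fully symmetrised outer product T (x) T of a symmetric 3x3 matrix,
# packed to 15 components: sym(T_ij T_kl) over the three pairings.
w15SymOuter <- function(tmat) {
  vapply(seq_len(15L), function(k) {
    ix <- .w15_idx[k, ]
    (tmat[ix[1], ix[2]] * tmat[ix[3], ix[4]] +
     tmat[ix[1], ix[3]] * tmat[ix[2], ix[4]] +
     tmat[ix[1], ix[4]] * tmat[ix[2], ix[3]]) / 3
  }, numeric(1))
}

# Deterministic eigen-decomposition of a symmetric 3x3 matrix: eigenvalues
# sorted descending; each eigenvector's sign fixed so its first component of
# largest magnitude is positive (lexicographic orientation on ties).
symEigen3 <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  for (k in 1:3) {
    v <- vecs[, k]
    lead <- which.max(abs(v))
    if (v[lead] < 0) vecs[, k] <- -v
  }
  list(values = vals, vectors = vecs)
}

# Axially symmetric tensor: axial eigenvalue along unit vector v, radial
# eigenvalue in the perpendicular plane.
axisymmetricTensor <- function(axial, radial, v) {
  (axial - radial) * tcrossprod(v) + radial * diag(3)
}
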