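# Scalar invariants of one tensor pair. `quad` is the fixed spherical
# quadrature (dirs + weights) for MK; RK averages `nPerp` equispaced
# directions perpendicular to the principal eigenvector; KA is the
# anisotropy of (K(e1), K(e2), K(e3)).
scalarValues <- function(tensors, quad = sphereQuadrature(),
                         nPerp = 64L, kaVariant = c("eigen", "sphere")) {
  kaVariant <- match.arg(kaVariant)
  out <- c(MD = NA_real_, FA = NA_real_, MK = NA_real_, AK = NA_real_,
           RK = NA_real_, KA = NA_real_)
  if (!all(is.finite(tensors$d6)) || !all(is.finite(tensors$w15)))
    return(list(values = out, validTensor = FALSE, validKurtosis = FALSE))
  dmat <- matrixFromD6(tensors$d6)
  eg <- symEigen3(dmat)
  lam <- eg$values
  md <- mean(lam)
  lbar <- md
  denom <- sum(lam^2)
  fa <- if (denom > 0) sqrt(1.5 * sum((lam - lbar)^2) / denom) else 0
  out["MD"] <- md
  out["FA"] <- fa
  if (md <= 0)
    return(list(values = out, validTensor = FALSE, validKurtosis = FALSE))
  # evaluate the spherical quadrature in the diffusion eigenframe so the
  # average co-rotates with the tensor (exact rotation invariance)
  ks <- apparentValues(tensors, quad$dirs %*% t(eg$vectors))
  if (anyNA(ks[, "K"]))
    return(list(values = out, validTensor = TRUE, validKurtosis = FALSE))
  out["MK"] <- sum(quad$weights * ks[, "K"])
  e1 <- eg$vectors[, 1]
  out["AK"] <- apparentValues(tensors, e1)[["K"]]
  perp <- perpendicularDirections(e1, nPerp)
  out["RK"] <- mean(apparentValues(tensors, perp)[, "K"])
  if (kaVariant == "eigen") {
    ke <- vapply(1:3, function(i)
      apparentValues(tensors, eg$vectors[, i])[["K"]], numeric(1))
    ssq <- sum(ke^2)
    out["KA"] <- if (ssq > 0) sqrt(1.5 * sum((ke - mean(ke))^2) / ssq) else 0
  } else {
    mu <- out[["MK"]]
    out["KA"] <- sqrt(sum(quad$weights * (ks[, "K"] - mu)^2))
  }
  list(values = out, validTensor = TRUE,
       validKurtosis = all(is.finite(out)))
}

#' Compute scalar diffusion-kurtosis maps from a tensor field
#'
#' Derives the six rotation-invariant scalars per voxel: MD and FA from the
#' diffusion-tensor eigenvalues
#' (\eqn{FA = \sqrt{3/2}\,\sqrt{\sum(\lambda_i-\bar\lambda)^2 / \sum\lambda_i^2}});
#' MK as the spherical average of the apparent kurtosis over a fixed
#' deterministic 250-node quadrature (Gauss-Legendre in the polar cosine
#' crossed with uniform azimuth, evaluated in the diffusion eigenframe so
#' the average co-rotates with the tensor); AK as the apparent kurtosis
#' along the principal
#' eigenvector; RK as the mean over 64 equispaced perpendicular directions;
#' and KA as an FA-style anisotropy of the three eigenvector-projected
#' kurtoses \eqn{K(e_1), K(e_2), K(e_3)} (variant `"eigen"`, the default).
#' KA definitions differ between toolchains; the alternative `"sphere"`
#' variant (standard deviation of K over the spherical set) is kept behind
#' the flag. Eigenvalues are sorted descending with a deterministic
#' eigenvector orientation, so AK/RK are reproducible on (near-)isotropic
#' voxels.
#'
#' @param field A [TensorField-class].
#' @param nSphere Size of the spherical direction set for MK.
#' @param nPerp Number of perpendicular directions for RK.
#' @param kaVariant `"eigen"` (default) or `"sphere"`.
#' @return A [ScalarMapSet-class]; voxels with non-finite tensor components
#'   are marked invalid.
#' @export
scalarMaps <- function(field, nSphere = 250L, nPerp = 64L,
                       kaVariant = c("eigen", "sphere")) {
  stopifnot(is(field, "TensorField"))
  kaVariant <- match.arg(kaVariant)
  nTheta <- max(4L, as.integer(round(sqrt(nSphere / 1.75))))
  quad <- sphereQuadrature(nTheta, as.integer(ceiling(nSphere / nTheta)))
  grid <- dim(field@s0)
  maps <- replicate(6, array(NA_real_, grid), simplify = FALSE)
  names(maps) <- c("MD", "FA", "MK", "AK", "RK", "KA")
  vT <- array(FALSE, grid)
  vK <- array(FALSE, grid)
  for (v in which(field@valid)) {
    sub <- arrayInd(v, grid)
    tp <- tensorAt(field, sub[1], sub[2], sub[3])
    sv <- scalarValues(tp, quad, nPerp, kaVariant)
    for (nm in names(maps)) maps[[nm]][v] <- sv$values[[nm]]
    vT[v] <- sv$validTensor
    vK[v] <- sv$validKurtosis
  }
  new("ScalarMapSet", md = maps$MD, fa = maps$FA, mk = maps$MK,
      ak = maps$AK, rk = maps$RK, ka = maps$KA,
      validTensor = vT, validKurtosis = vK, voxelSize = field@voxelSize)
}

#' Apply the mean-kurtosis quality-control deletion rule
#'
#' Voxels whose MK is strictly below `lower` or strictly above `upper`
#' (defaults 0 and 3) are deleted from the validity mask shared by all
#' kurtosis-family maps (MK, AK, RK, KA and any downstream tract-integrity
#' maps that consume `validKurtosis`). Boundary values are retained: the
#' rule is a strict inequality. MD and FA keep their own tensor-validity
#' mask, which the rule does not touch.
#'
#' @param maps A [ScalarMapSet-class].
#' @param lower,upper QC thresholds on MK.
#' @return The map set with an updated `validKurtosis` mask; the number of
#'   deleted voxels is reported via `message()`.
#' @export
qcFilter <- function(maps, lower = 0, upper = 3) {
  stopifnot(is(maps, "ScalarMapSet"), lower < upper)
  bad <- maps@validKurtosis & is.finite(maps@mk) &
    (maps@mk < lower | maps@mk > upper)
  maps@validKurtosis <- maps@validKurtosis & !bad
  message(sum(bad), " voxels deleted by the MK (", lower, ", ", upper,
          ") rule")
  maps
}
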