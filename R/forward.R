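#' Exact diffusion and kurtosis tensors of a two-compartment voxel
#'
#' Computes the diffusion tensor and MD^2-normalised kurtosis tensor of a
#' mixture of two Gaussian compartments (intra-axonal fraction `f`,
#' extra-axonal fraction `1 - f`) from the exact mixture cumulants:
#' \deqn{D = f D_a + (1-f) D_e}
#' \deqn{W_{ijkl} = \frac{3}{MD^2}\,\mathrm{sym}\!\left[f D_a \otimes D_a +
#'   (1-f) D_e \otimes D_e - D \otimes D\right]}
#' so that along any unit direction n,
#' \eqn{K(n) = 3 f (1-f) (D_a(n) - D_e(n))^2 / D(n)^2}. The result is exact
#' ground truth for estimator recovery tests: no directional sampling is
#' involved.
#'
#' @param params A [TissueParams-class] object.
#' @return A list with elements `d6` (packed diffusion tensor), `w15`
#'   (packed kurtosis tensor), `md` (mean diffusivity) — a "tensor pair".
#' @examples
#' p <- tissueParams(f = 0.3, daAx = 0.8, deAx = 2.0, deRad = 0.8)
#' tp <- wmtiForward(p)
#' # apparent kurtosis along the fiber: 3*0.3*0.7*(0.8-2.0)^2 / 1.64^2
#' apparentValues(tp, c(1, 0, 0))
#' @export
wmtiForward <- function(params) {
  stopifnot(is(params, "TissueParams"))
  validObject(params)
  f <- params@f
  v <- params@orientation
  da <- axisymmetricTensor(params@daAx, params@radIad, v)
  de <- axisymmetricTensor(params@deAx, params@deRad, v)
  d <- f * da + (1 - f) * de
  md <- sum(diag(d)) / 3
  if (md <= 0) {
    w15 <- rep(0, 15)
  } else {
    w15 <- 3 / md^2 * (f * w15SymOuter(da) + (1 - f) * w15SymOuter(de) -
                         w15SymOuter(d))
  }
  list(d6 = d6FromMatrix(d), w15 = w15, md = md)
}

#' Noise-free multi-shell signal from a tensor pair
#'
#' Evaluates the truncated-cumulant (diffusion-kurtosis) signal model
#' \deqn{S(b, n) = S_0 \exp\left(-b D(n) + \tfrac{1}{6} b^2 MD^2 W(n)\right)}
#' for every volume of an acquisition scheme. b-factors are supplied in
#' s/mm^2 and converted internally to ms/micrometre^2 to match diffusivities
#' in micrometre^2/ms. This is exactly the model inverted by [fitVoxel()],
#' so noise-free round trips are exact to solver precision.
#'
#' @param tensors A tensor pair as returned by [wmtiForward()] (list with
#'   `d6`, `w15`; `md` is recomputed if absent).
#' @param scheme An [AcquisitionScheme-class].
#' @param s0 Baseline signal (> 0).
#' @return Numeric vector of per-volume signals.
#' @export
forwardSignal <- function(tensors, scheme, s0 = 1000) {
  stopifnot(is(scheme, "AcquisitionScheme"), s0 > 0)
  b <- scheme@bvalues / 1000  # ms/um^2
  if (any(b < 0)) stop("invalid b-factor")
  md <- tensors$md
  if (is.null(md)) md <- sum(tensors$d6[1:3]) / 3
  dirs <- t(scheme@bvectors)
  dn <- as.vector(dQuadRows(dirs) %*% tensors$d6)
  wn <- as.vector(wQuartRows(dirs) %*% tensors$w15)
  s0 * exp(-b * dn + (b^2 / 6) * md^2 * wn)
}

#' Apparent diffusion and kurtosis along a direction
#'
#' Directional projections of a tensor pair:
#' \eqn{D(n) = \sum n_i n_j D_{ij}} and
#' \eqn{K(n) = (MD^2 / D(n)^2) \sum n_i n_j n_k n_l W_{ijkl}}.
#'
#' @param tensors Tensor pair (list with `d6`, `w15`, optionally `md`).
#' @param n Unit direction (3-vector) or an m x 3 matrix of directions.
#' @return For a single direction, `c(D = , K = )`; for a matrix, a
#'   two-column matrix. `K` is `NA` where `D(n) <= 0` (the voxel is flagged
#'   invalid for directional metrics).
#' @export
apparentValues <- function(tensors, n) {
  if (is.null(dim(n))) n <- matrix(n, 1, 3)
  md <- tensors$md
  if (is.null(md)) md <- sum(tensors$d6[1:3]) / 3
  dn <- as.vector(dQuadRows(n) %*% tensors$d6)
  wn <- as.vector(wQuartRows(n) %*% tensors$w15)
  k <- ifelse(dn > 0, md^2 * wn / dn^2, NA_real_)
  if (nrow(n) == 1L) c(D = dn, K = k) else cbind(D = dn, K = k)
}
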