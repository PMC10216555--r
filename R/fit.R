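#' Design matrix of the log-linearised diffusion-kurtosis model
#'
#' Assembles the regression matrix of
#' \deqn{\ln S = \ln S_0 - b \sum_{ij} n_i n_j D_{ij}
#'   + \tfrac{b^2}{6} \sum_{ijkl} n_i n_j n_k n_l V_{ijkl}}
#' with \eqn{V = MD^2 W} recovered after the linear solve. Column order is
#' fixed: `lnS0`, the 6 diffusion components ([dComponentNames()], with
#' off-diagonal multiplicity 2 absorbed into the column), then the 15
#' quartic components ([wComponentNames()], multiplicities absorbed).
#' b-factors are converted to ms/micrometre^2 internally.
#'
#' @param scheme An [AcquisitionScheme-class].
#' @return A `nVolumes x 22` matrix of full column rank (an error is raised
#'   for degenerate schemes).
#' @export
buildDesign <- function(scheme) {
  stopifnot(is(scheme, "AcquisitionScheme"))
  validObject(scheme)
  b <- scheme@bvalues / 1000
  dirs <- t(scheme@bvectors)
  x <- cbind(1, -b * dQuadRows(dirs), (b^2 / 6) * wQuartRows(dirs))
  colnames(x) <- c("lnS0", dComponentNames(), wComponentNames())
  if (qr(x)$rank < ncol(x)) stop("degenerate design")
  x
}

#' Fit the diffusion and kurtosis tensors in one voxel
#'
#' Linear least squares on log-signals. The default is a two-pass
#' signal-weighted fit: an unweighted pass predicts the noise-free signals,
#' whose squares weight the second pass (the standard correction for the
#' heteroscedasticity introduced by the log transform). Both variants are
#' exact on noise-free model signals. Signals at or below `minSignal` are
#' clamped before the log and down-weighted to (near) zero in the weighted
#' pass.
#'
#' @param signals Per-volume intensities (length `nrow(design)`).
#' @param design Design matrix from [buildDesign()].
#' @param weighting `"wlls"` (two-pass signal-weighted, default) or
#'   `"olls"` (unweighted).
#' @param minSignal Positive clamp for the log transform; signals below it
#'   are treated as censored.
#' @return A list: `d6`, `w15`, `md`, `s0`, `valid`. If every signal is at
#'   or below `minSignal` (or the solve degenerates) the voxel is returned
#'   with `valid = FALSE` rather than raising an error.
#' @export
fitVoxel <- function(signals, design, weighting = c("wlls", "olls"),
                     minSignal = NULL) {
  weighting <- match.arg(weighting)
  if (is.null(minSignal)) minSignal <- 1e-6 * max(signals, 1e-300)
  stopifnot(minSignal > 0, length(signals) == nrow(design))
  invalid <- list(d6 = rep(NA_real_, 6), w15 = rep(NA_real_, 15),
                  md = NA_real_, s0 = NA_real_, valid = FALSE)
  ok <- is.finite(signals) & signals > minSignal
  if (!any(ok)) return(invalid)
  s <- pmax(signals, minSignal)
  s[!is.finite(s)] <- minSignal
  y <- log(s)
  fit1 <- stats::lm.fit(design, y)
  beta <- fit1$coefficients
  if (anyNA(beta)) return(invalid)
  if (weighting == "wlls") {
    w <- exp(as.vector(design %*% beta))^2
    w[!ok] <- w[!ok] * 1e-12  # clamped rows carry no real information
    fit2 <- stats::lm.wfit(design, y, w)
    if (!anyNA(fit2$coefficients)) beta <- fit2$coefficients
  }
  d6 <- beta[2:7]
  v15 <- beta[8:22]
  md <- sum(d6[1:3]) / 3
  if (!is.finite(md) || md <= 0) return(invalid)
  list(d6 = unname(d6), w15 = unname(v15) / md^2, md = md,
       s0 = exp(beta[[1]]), valid = TRUE)
}

#' Fit the tensor field of a 4-D volume
#'
#' Applies [fitVoxel()] to every in-mask voxel of a 4-D multi-shell volume.
#'
#' @param dwi 4-D array; the last axis indexes volumes and must match the
#'   scheme length.
#' @param scheme An [AcquisitionScheme-class].
#' @param mask Optional 3-D logical array of voxels to fit (default: voxels
#'   with positive first-volume signal).
#' @param weighting,minSignal Passed to [fitVoxel()]; `minSignal` defaults
#'   to `1e-6 * max(dwi)`.
#' @param voxelSize Voxel edge lengths in mm, stored in the result.
#' @return A [TensorField-class]. The number of invalid in-mask voxels is
#'   reported via `message()`.
#' @export
fitVolume <- function(dwi, scheme, mask = NULL,
                      weighting = c("wlls", "olls"), minSignal = NULL,
                      voxelSize = c(2.5, 2.5, 2.5)) {
  weighting <- match.arg(weighting)
  dims <- dim(dwi)
  if (length(dims) != 4L || dims[4] != nVolumes(scheme))
    stop("scheme/volume mismatch: volume has ", paste(dims, collapse = "x"),
         ", scheme has ", nVolumes(scheme), " entries")
  if (is.null(minSignal)) minSignal <- 1e-6 * max(dwi, 1e-300)
  if (is.null(mask)) mask <- array(dwi[, , , 1] > 0, dims[1:3])
  stopifnot(identical(dim(mask), dims[1:3]))
  x <- buildDesign(scheme)
  grid <- dims[1:3]
  d <- array(NA_real_, c(grid, 6L))
  w <- array(NA_real_, c(grid, 15L))
  s0 <- array(NA_real_, grid)
  valid <- array(FALSE, grid)
  sigmat <- matrix(dwi, prod(grid), dims[4])
  idx <- which(mask)
  for (v in idx) {
    res <- fitVoxel(sigmat[v, ], x, weighting = weighting,
                    minSignal = minSignal)
    if (res$valid) {
      sub <- arrayInd(v, grid)
      d[sub[1], sub[2], sub[3], ] <- res$d6
      w[sub[1], sub[2], sub[3], ] <- res$w15
      s0[sub[1], sub[2], sub[3]] <- res$s0
      valid[v] <- TRUE
    }
  }
  nbad <- length(idx) - sum(valid)
  if (nbad > 0)
    message(nbad, " of ", length(idx), " in-mask voxels invalid after fit")
  new("TensorField", d = d, w = w, s0 = s0, valid = valid,
      voxelSize = voxelSize)
}

# Extract one voxel of a TensorField as a tensor pair list.
tensorAt <- function(field, i, j, k) {
  d6 <- field@d[i, j, k, ]
  list(d6 = d6, w15 = field@w[i, j, k, ], md = sum(d6[1:3]) / 3)
}
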