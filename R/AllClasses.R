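#' @import methods
NULL

#' Multi-shell acquisition scheme
#'
#' Per-volume b-factors and unit gradient directions of a multi-shell
#' diffusion acquisition. Estimating the kurtosis tensor on top of the
#' diffusion tensor requires at least two distinct nonzero shells and at
#' least 21 nonzero-b measurements (the diffusion-plus-kurtosis linear model
#' has 22 unknowns including the baseline).
#'
#' @slot bvalues Numeric vector of b-factors, s/mm^2, one per volume.
#' @slot bvectors 3 x n matrix of gradient directions (columns); unit norm
#'   for b > 0, zero column allowed for b = 0.
#' @export
setClass("AcquisitionScheme",
         representation(bvalues = "numeric", bvectors = "matrix"))

setValidity("AcquisitionScheme", function(object) {
  b <- object@bvalues
  g <- object@bvectors
  if (nrow(g) != 3L || ncol(g) != length(b))
    return("bvectors must be a 3 x length(bvalues) matrix")
  if (any(b < 0)) return("negative b-factor")
  nz <- b > 0
  if (!any(!nz)) return("at least one b=0 volume required")
  if (length(unique(b[nz])) < 2L)
    return("insufficient shells for kurtosis")
  if (sum(nz) < 21L)
    return("fewer than 21 nonzero-b measurements: under-determined")
  norms <- sqrt(colSums(g[, nz, drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6))
    return("non-unit gradient direction on nonzero shell")
  TRUE
})

#' Fitted diffusion + kurtosis tensor field
#'
#' Voxel grid of packed diffusion tensors (6 components, micrometre^2/ms),
#' MD^2-normalised kurtosis tensors (15 components, dimensionless), fitted
#' baselines, and a per-voxel validity mask. Component orders are those of
#' [dComponentNames()] and [wComponentNames()].
#'
#' @slot d 4-D array (x, y, z, 6) of diffusion-tensor components.
#' @slot w 4-D array (x, y, z, 15) of kurtosis-tensor components.
#' @slot s0 3-D array of fitted baseline signals.
#' @slot valid 3-D logical array; FALSE where the fit failed or was masked.
#' @slot voxelSize Voxel edge lengths in mm.
#' @export
setClass("TensorField",
         representation(d = "array", w = "array", s0 = "array",
                        valid = "array", voxelSize = "numeric"))

setValidity("TensorField", function(object) {
  dd <- dim(object@d)
  if (length(dd) != 4L || dd[4] != 6L) return("d must be (x,y,z,6)")
  dw <- dim(object@w)
  if (length(dw) != 4L || dw[4] != 15L) return("w must be (x,y,z,15)")
  if (!identical(dd[1:3], dw[1:3])) return("d/w grid mismatch")
  if (!identical(dd[1:3], dim(object@s0))) return("s0 grid mismatch")
  if (!identical(dd[1:3], dim(object@valid))) return("valid grid mismatch")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive lengths")
  TRUE
})

#' Scalar diffusion-kurtosis maps
#'
#' Voxel maps of the six scalar invariants (MD in micrometre^2/ms; FA, MK,
#' AK, RK, KA dimensionless) plus two validity masks: `validTensor` for the
#' diffusion-tensor-only maps (MD, FA) and `validKurtosis` for the
#' kurtosis-family maps, which is further reduced by [qcFilter()].
#'
#' @slot md,fa,mk,ak,rk,ka 3-D arrays, one value per voxel.
#' @slot validTensor,validKurtosis 3-D logical arrays.
#' @slot voxelSize Voxel edge lengths in mm.
#' @export
setClass("ScalarMapSet",
         representation(md = "array", fa = "array", mk = "array",
                        ak = "array", rk = "array", ka = "array",
                        validTensor = "array", validKurtosis = "array",
                        voxelSize = "numeric"))

setValidity("ScalarMapSet", function(object) {
  dims <- dim(object@md)
  for (nm in c("fa", "mk", "ak", "rk", "ka", "validTensor", "validKurtosis"))
    if (!identical(dim(slot(object, nm)), dims))
      return(sprintf("map '%s' not on the shared grid", nm))
  ok <- object@validTensor & is.finite(object@fa)
  if (any(object@fa[ok] < -1e-9 | object@fa[ok] > 1 + 1e-9))
    return("FA outside [0,1] on valid voxels")
  TRUE
})

#' White-matter tract-integrity maps
#'
#' Two-compartment parameter maps derived from a fitted tensor field: axonal
#' water fraction (AWF), axial/radial extra- and intra-axonal diffusivities
#' (micrometre^2/ms) and extra-axonal tortuosity. `valid` marks voxels where
#' the inversion ran; `validIntra` additionally excludes voxels with no
#' detectable restricted compartment (AWF below threshold), where the
#' intra-axonal maps and TORT are undefined.
#'
#' @slot awf,axEAD,radEAD,axIAD,radIAD,tort 3-D arrays.
#' @slot valid,validIntra 3-D logical arrays.
#' @slot voxelSize Voxel edge lengths in mm.
#' @export
setClass("WMTIMapSet",
         representation(awf = "array", axEAD = "array", radEAD = "array",
                        axIAD = "array", radIAD = "array", tort = "array",
                        valid = "array", validIntra = "array",
                        voxelSize = "numeric"))

setValidity("WMTIMapSet", function(object) {
  dims <- dim(object@awf)
  for (nm in c("axEAD", "radEAD", "axIAD", "radIAD", "tort",
               "valid", "validIntra"))
    if (!identical(dim(slot(object, nm)), dims))
      return(sprintf("map '%s' not on the shared grid", nm))
  ok <- object@valid
  aw <- object@awf[ok]
  if (any(is.finite(aw) & (aw < 0 | aw >= 1)))
    return("AWF outside [0,1) on valid voxels")
  TRUE
})

#' Single-zone tissue parameters for the two-compartment forward model
#'
#' Ground-truth microstructure of one phantom zone: an intra-axonal
#' compartment (fraction `f`, cylindrically symmetric, axial diffusivity
#' `daAx`, radial diffusivity `radIad`, 0 by default) and an extra-axonal
#' compartment (axially symmetric, `deAx` / `deRad`), sharing one fiber
#' `orientation`. Diffusivities in micrometre^2/ms.
#'
#' @slot f Axonal water fraction in [0, 1).
#' @slot daAx,radIad Intra-axonal axial and radial diffusivities.
#' @slot deAx,deRad Extra-axonal axial and radial diffusivities.
#' @slot orientation Unit 3-vector, principal fiber axis.
#' @export
setClass("TissueParams",
         representation(f = "numeric", daAx = "numeric", radIad = "numeric",
                        deAx = "numeric", deRad = "numeric",
                        orientation = "numeric"))

setValidity("TissueParams", function(object) {
  if (object@f < 0 || object@f >= 1) return("invalid fraction")
  if (any(c(object@daAx, object@radIad, object@deAx, object@deRad) < 0))
    return("negative diffusivity")
  if (abs(sqrt(sum(object@orientation^2)) - 1) > 1e-6)
    return("orientation must be unit norm")
  TRUE
})

#' Specification of the four-zone image phantom
#'
#' Geometry, per-zone tissue parameters, perfusion statistics, baseline
#' signal and noise level of the synthetic multi-shell image. Zone labels:
#' 1 enhancing tumor core, 2 perifocal infiltrative edema, 3 ipsilateral
#' normal-appearing white matter, 4 contralateral white matter, 0
#' background. Zone 4 is spatially disjoint from zones 1-3.
#'
#' @slot dim Grid size (3 integers).
#' @slot voxelSize Voxel edge lengths, mm.
#' @slot labels 3-D integer array of zone labels (values 0-4).
#' @slot zones List of 4 [TissueParams-class] objects, one per zone label.
#' @slot cbfMean,cbfSD Per-zone CBF mean and spread, mL/100 g/min.
#' @slot s0 Baseline signal.
#' @slot snr Baseline signal-to-noise ratio s0/sigma; `Inf` for noise-free.
#' @slot roiAreaMM2 Target in-plane ROI patch area, mm^2.
#' @slot noiseModel "rician" or "gaussian".
#' @slot seed Integer seed for all randomness in the image simulation.
#' @export
setClass("PhantomSpec",
         representation(dim = "integer", voxelSize = "numeric",
                        labels = "array", zones = "list",
                        cbfMean = "numeric", cbfSD = "numeric",
                        s0 = "numeric", snr = "numeric",
                        roiAreaMM2 = "numeric", noiseModel = "character",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (!identical(dim(object@labels), object@dim))
    return("labels grid does not match dim")
  labs <- sort(unique(as.integer(object@labels)))
  if (!all(labs %in% 0:4)) return("labels must be in {0,1,2,3,4}")
  if (length(object@zones) != 4L)
    return("zones must list TissueParams for labels 1-4")
  for (z in 1:4)
    if (any(object@labels == z) && !is(object@zones[[z]], "TissueParams"))
      return(sprintf("unparameterized zone %d", z))
  if (length(object@cbfMean) != 4L || length(object@cbfSD) != 4L)
    return("cbfMean/cbfSD must have length 4")
  if (any(object@cbfSD < 0)) return("negative CBF spread")
  if (object@s0 <= 0) return("s0 must be positive")
  if (object@snr <= 0) return("snr must be positive")
  if (!object@noiseModel %in% c("rician", "gaussian"))
    return("noiseModel must be 'rician' or 'gaussian'")
  TRUE
})

#' Specification of the simulated patient cohort
#'
#' Per-zone, per-parameter normal means and standard deviations for the 13
#' quantitative values (12 diffusion-kurtosis parameters + CBF), the number
#' of cases, and the marker model: target Spearman correlations between
#' stated ROI parameter values and immunohistochemical markers, realised
#' through a Gaussian copula.
#'
#' @slot nCases Number of simulated cases (>= 3).
#' @slot means,sds 4 x 13 matrices (rows = zones 1-4, columns named by
#'   [quantParamNames()]).
#' @slot markerLinks data.frame with columns `marker`, `roi`, `parameter`,
#'   `rho` (target Spearman, in [-1, 1]).
#' @slot seed Integer seed.
#' @export
setClass("CohortSpec",
         representation(nCases = "integer", means = "matrix", sds = "matrix",
                        markerLinks = "data.frame", seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@nCases < 3L) return("nCases must be at least 3")
  if (!identical(dim(object@means), c(4L, 13L)) ||
      !identical(dim(object@sds), c(4L, 13L)))
    return("means/sds must be 4 x 13")
  if (any(object@sds < 0)) return("standard deviations must be >= 0")
  ml <- object@markerLinks
  need <- c("marker", "roi", "parameter", "rho")
  if (nrow(ml) > 0 && !all(need %in% names(ml)))
    return("markerLinks needs columns marker, roi, parameter, rho")
  if (nrow(ml) > 0 && any(abs(ml$rho) > 1))
    return("target correlations must lie in [-1, 1]")
  TRUE
})

#' @describeIn AcquisitionScheme-class Number of volumes in the scheme.
#' @param object,x An object of the documented class.
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @export
setMethod("nVolumes", "AcquisitionScheme", function(x) length(x@bvalues))

#' @export
setGeneric("bvalues", function(x) standardGeneric("bvalues"))

#' @export
setMethod("bvalues", "AcquisitionScheme", function(x) x@bvalues)

#' @export
setGeneric("bvectors", function(x) standardGeneric("bvectors"))

#' @export
setMethod("bvectors", "AcquisitionScheme", function(x) x@bvectors)

#' Extract the per-voxel validity mask of a map container
#' @param x A TensorField, ScalarMapSet or WMTIMapSet.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @export
setMethod("validMask", "TensorField", function(x) x@valid)

#' @export
setMethod("validMask", "ScalarMapSet", function(x) x@validKurtosis)

#' @export
setMethod("validMask", "WMTIMapSet", function(x) x@valid)

#' Extract named scalar maps as a list of 3-D arrays
#' @param x A ScalarMapSet or WMTIMapSet.
#' @export
setGeneric("mapList", function(x) standardGeneric("mapList"))

#' @export
setMethod("mapList", "ScalarMapSet", function(x) {
  list(MD = x@md, FA = x@fa, MK = x@mk, AK = x@ak, RK = x@rk, KA = x@ka)
})

#' @export
setMethod("mapList", "WMTIMapSet", function(x) {
  list(AWF = x@awf, AxEAD = x@axEAD, AxIAD = x@axIAD,
       RadEAD = x@radEAD, RadIAD = x@radIAD, TORT = x@tort)
})

setMethod("show", "AcquisitionScheme", function(object) {
  b <- object@bvalues
  shells <- sort(unique(b))
  cat("AcquisitionScheme:", length(b), "volumes\n")
  for (s in shells)
    cat(sprintf("  b = %6g s/mm^2 : %d volumes\n", s, sum(b == s)))
})

setMethod("show", "TensorField", function(object) {
  cat("TensorField on grid", paste(dim(object@s0), collapse = " x "),
      sprintf("(%d/%d voxels valid)\n",
              sum(object@valid), length(object@valid)))
})

setMethod("show", "ScalarMapSet", function(object) {
  cat("ScalarMapSet (MD, FA, MK, AK, RK, KA) on grid",
      paste(dim(object@md), collapse = " x "), "\n")
  cat(sprintf("  tensor-valid %d, kurtosis-valid %d of %d voxels\n",
              sum(object@validTensor), sum(object@validKurtosis),
              length(object@md)))
})

setMethod("show", "WMTIMapSet", function(object) {
  cat("WMTIMapSet (AWF, AxEAD, AxIAD, RadEAD, RadIAD, TORT) on grid",
      paste(dim(object@awf), collapse = " x "), "\n")
  cat(sprintf("  valid %d, intra-compartment valid %d of %d voxels\n",
              sum(object@valid), sum(object@validIntra), length(object@awf)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@dim, collapse = " x "), "grid,",
      "snr =", object@snr, ", noise =", object@noiseModel,
      ", seed =", object@seed, "\n")
  cat("  zone voxels:",
      paste(vapply(1:4, function(z) sum(object@labels == z), 0L),
            collapse = ", "), "\n")
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nCases, "cases, 4 zones x 13 parameters,",
      nrow(object@markerLinks), "marker links, seed", object@seed, "\n")
})

#' Canonical parameter names of the quantitative battery
#'
#' The 12 diffusion-kurtosis parameters followed by CBF, in the column
#' order used by ROI tables and the cohort simulator.
#' @return Character vector of length 13.
#' @export
quantParamNames <- function() {
  c("MD", "FA", "MK", "AK", "RK", "KA",
    "AWF", "AxEAD", "AxIAD", "RadEAD", "RadIAD", "TORT", "CBF")
}

#' Construct tissue parameters for one phantom zone
#'
#' @param f Axonal water fraction in [0, 1).
#' @param daAx Intra-axonal axial diffusivity (micrometre^2/ms).
#' @param deAx,deRad Extra-axonal axial and radial diffusivities.
#' @param radIad Intra-axonal radial diffusivity (0 for ideal cylinders).
#' @param orientation Unit 3-vector fiber axis.
#' @return A [TissueParams-class] object.
#' @examples
#' tissueParams(f = 0.3, daAx = 0.8, deAx = 2.0, deRad = 0.8)
#' @export
tissueParams <- function(f, daAx, deAx, deRad, radIad = 0,
                         orientation = c(1, 0, 0)) {
  if (f < 0 || f >= 1) stop("invalid fraction")
  orientation <- orientation / sqrt(sum(orientation^2))
  new("TissueParams", f = f, daAx = daAx, radIad = radIad,
      deAx = deAx, deRad = deRad, orientation = orientation)
}
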