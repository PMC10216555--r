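# Per-zone standard deviations of the default cohort. Calibrated once
# against the published combined-group discrimination profile through the
# binormal relation AUC = pnorm(delta / sqrt(sd_a^2 + sd_b^2)), so that the
# expected AUC ordering of the simulated cohort mirrors the clinical one:
# CBF dominates the core-vs-edema contrast while MK, RK and AWF dominate
# the edema-vs-NAWM and NAWM-vs-contralateral contrasts. Tumor zones are
# the most variable, the contralateral zone the tightest.
defaultCohortSDs <- function() {
  m <- rbind(
    zone1 = c(MD = 0.70, FA = 0.28, MK = 0.47, AK = 0.105, RK = 1.00,
              KA = 0.140, AWF = 0.180, AxEAD = 0.33, AxIAD = 0.12,
              RadEAD = 0.72, RadIAD = 0.05, TORT = 0.90, CBF = 24),
    zone2 = c(MD = 0.22, FA = 0.15, MK = 0.21, AK = 0.105, RK = 0.50,
              KA = 0.045, AWF = 0.077, AxEAD = 0.23, AxIAD = 0.12,
              RadEAD = 0.33, RadIAD = 0.05, TORT = 0.47, CBF = 15),
    zone3 = c(MD = 0.22, FA = 0.15, MK = 0.21, AK = 0.105, RK = 0.50,
              KA = 0.045, AWF = 0.077, AxEAD = 0.23, AxIAD = 0.12,
              RadEAD = 0.33, RadIAD = 0.05, TORT = 0.47, CBF = 15),
    zone4 = c(MD = 0.10, FA = 0.03, MK = 0.05, AK = 0.105, RK = 0.10,
              KA = 0.025, AWF = 0.018, AxEAD = 0.23, AxIAD = 0.12,
              RadEAD = 0.36, RadIAD = 0.05, TORT = 0.90, CBF = 5))
  m[, quantParamNames()]
}

#' Default marker model of the simulated cohort
#'
#' Target Spearman correlations between ROI parameter values and
#' immunohistochemical markers, matching the significant combined-group
#' correlations reported for high-grade glioma: in the enhancing core
#' (ROI 1) the Ki-67 labelling index correlates with CBF (0.363), AWF
#' (0.343) and RK (0.324); in the infiltrative edema (ROI 2) Bcl-2
#' expression anticorrelates with MK (-0.444) and RK (-0.427).
#'
#' @return data.frame with columns `marker`, `roi`, `parameter`, `rho`.
#' @export
defaultMarkerLinks <- function() {
  data.frame(
    marker = c("Ki67_LI", "Ki67_LI", "Ki67_LI", "Bcl2_EA", "Bcl2_EA"),
    roi = c(1L, 1L, 1L, 2L, 2L),
    parameter = c("CBF", "AWF", "RK", "MK", "RK"),
    rho = c(0.363, 0.343, 0.324, -0.444, -0.427),
    stringsAsFactors = FALSE)
}

#' Construct a cohort specification
#'
#' Defaults: 50 cases (the reference clinical cohort size), per-zone means
#' equal to the closed-form phantom ground truth ([zoneTruth()]), SDs
#' calibrated to the published zone-discrimination profile, and the
#' [defaultMarkerLinks()] marker model.
#'
#' @param nCases Number of cases (>= 3).
#' @param means,sds 4 x 13 matrices (zones x [quantParamNames()]).
#' @param markerLinks Marker model data.frame (may have zero rows).
#' @param seed Integer seed.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nCases = 50L, means = zoneTruth(phantomSpec()),
                       sds = defaultCohortSDs(),
                       markerLinks = defaultMarkerLinks(), seed = 1L) {
  means <- as.matrix(means)[, quantParamNames(), drop = FALSE]
  sds <- as.matrix(sds)[, quantParamNames(), drop = FALSE]
  dimnames(means) <- dimnames(sds) <-
    list(paste0("zone", 1:4), quantParamNames())
  new("CohortSpec", nCases = as.integer(nCases), means = means, sds = sds,
      markerLinks = markerLinks, seed = as.integer(seed))
}

#' Simulate a cohort-level ROI table with marker columns
#'
#' Draws, for each case and zone, the 13 quantitative parameters from the
#' per-zone normal distributions of the spec (parameters mutually
#' independent given the zone), then generates immunohistochemical marker
#' values through a Gaussian copula: each marker's latent normal score is a
#' linear blend of the standardised scores of the parameters it targets,
#' with loadings \eqn{r_j = 2 \sin(\pi \rho_j / 6)} chosen so the
#' *Spearman* correlation with each target equals \eqn{\rho_j} in
#' expectation; the latent score is then pushed through a strictly monotone
#' transform to realistic marker units (a logistic map to percent for the
#' Ki-67 labelling index, an exponential map for expression activities),
#' which leaves all rank correlations untouched. Markers are emitted for
#' ROIs 1-3 only, mirroring the biopsy protocol; an infeasible loading
#' vector (summed squared loadings above 1) is rejected as an invalid
#' marker model. All draws are governed by the spec seed.
#'
#' @param spec A [CohortSpec-class].
#' @return A data.frame with one row per case x ROI: `case_id`, `roi`, the
#'   13 parameter columns, and one column per marker named in the links
#'   (plus `Ki67_LI`/`Bcl2_EA` by default).
#' @examples
#' tab <- simulateCohort(cohortSpec(nCases = 10, seed = 7))
#' head(tab)
#' @export
simulateCohort <- function(spec = cohortSpec()) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nCases
  pn <- quantParamNames()
  vals <- array(NA_real_, c(n, 4L, 13L), dimnames = list(NULL, NULL, pn))
  for (z in 1:4)
    for (p in pn)
      vals[, z, p] <- stats::rnorm(n, spec@means[z, p], spec@sds[z, p])
  markers <- unique(spec@markerLinks$marker)
  if (length(markers) == 0L) markers <- c("Ki67_LI", "Bcl2_EA")
  mvals <- array(NA_real_, c(n, 4L, length(markers)),
                 dimnames = list(NULL, NULL, markers))
  for (mk in markers) {
    for (z in 1:3) {  # biopsies exist for ROIs 1-3 only
      links <- spec@markerLinks[spec@markerLinks$marker == mk &
                                  spec@markerLinks$roi == z, , drop = FALSE]
      loads <- 2 * sin(pi * links$rho / 6)
      if (sum(loads^2) > 1) stop("invalid marker model")
      latent <- stats::rnorm(n) * sqrt(1 - sum(loads^2))
      if (nrow(links) > 0) {
        zscores <- sapply(seq_len(nrow(links)), function(j) {
          p <- links$parameter[j]
          (vals[, z, p] - spec@means[z, p]) / spec@sds[z, p]
        })
        latent <- latent + as.vector(zscores %*% loads)
      }
      mvals[, z, mk] <- markerTransform(mk, z, latent)
    }
  }
  rows <- expand.grid(roi = 1:4, case = seq_len(n))
  out <- data.frame(case_id = sprintf("case%03d", rows$case),
                    roi = rows$roi, stringsAsFactors = FALSE)
  for (p in pn) out[[p]] <- vals[cbind(rows$case, rows$roi,
                                       match(p, pn))]
  for (mk in markers) out[[mk]] <- mvals[cbind(rows$case, rows$roi,
                                               match(mk, markers))]
  out
}

# Strictly monotone maps from the latent normal score to marker units:
# logistic to percent for the proliferation index (zone-specific level,
# decreasing core -> edema -> NAWM), exponential for expression activities.
# Monotonicity preserves every Spearman correlation by construction.
markerTransform <- function(marker, zone, latent) {
  if (marker == "Ki67_LI") {
    loc <- c(-1.0, -2.2, -4.0)[zone]
    100 * stats::plogis(loc + 0.8 * latent)
  } else {
    loc <- c(1.6, 1.0, 0.2)[zone]
    exp(loc + 0.6 * latent)
  }
}
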