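# NIfTI helpers: every derived map is written on the input grid, carrying
# the reference image's affine and voxel sizes unchanged.
writeNiftiMap <- function(arr, path, reference = NULL,
                          voxelSize = c(2.5, 2.5, 2.5)) {
  img <- if (is.null(reference)) {
    x <- RNifti::asNifti(arr)
    # the image may collapse trailing singleton axes; match its rank
    RNifti::pixdim(x) <- rep_len(voxelSize, length(dim(x)))
    x
  } else {
    RNifti::asNifti(arr, reference = reference)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

# NIfTI readers drop trailing singleton dimensions; restore a 3-D grid.
ensure3d <- function(a) {
  d <- dim(a)
  if (length(d) == 2L) dim(a) <- c(d, 1L)
  a
}

readNiftiArray <- function(path) {
  img <- RNifti::readNifti(path)
  structure(as.array(img), pixdim = RNifti::pixdim(img))
}

#' Default pipeline configuration
#'
#' Returns the full option list consumed by [runPipeline()], with the
#' package defaults filled in: two-pass weighted fit, eigenvector KA over a
#' 250-direction sphere, the (0, 3) MK deletion rule, adjacent-pair
#' comparisons at alpha 0.001, correlations at alpha 0.05, 2000 bootstrap
#' replications.
#'
#' @return Named list of options; override entries via [runPipeline()]'s
#'   `config`.
#' @export
defaultPipelineConfig <- function() {
  list(
    dwi = NULL, bval = NULL, bvec = NULL, cbf = NULL, roi = NULL,
    mask = NULL, table = NULL, out = NULL, caseId = "case",
    fit = list(weighting = "wlls"),
    metrics = list(kaVariant = "eigen", nSphere = 250L, nPerp = 64L),
    qc = list(lower = 0, upper = 3),
    stats = list(pairs = list(c(1L, 2L), c(2L, 3L), c(3L, 4L)),
                 alphaCompare = 0.001, alphaCorrelate = 0.05,
                 nBoot = 2000L, seed = 1L))
}

mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]])))
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full single-case analysis pipeline
#'
#' Orchestrates the stage sequence fit -> scalar maps -> QC -> tract
#' integrity -> ROI means (-> cohort statistics -> report) on co-registered
#' inputs, writing every artifact under `config$out`: the tensor field and
#' validity mask, all scalar and tract-integrity maps as NIfTI on the input
#' grid, the per-case ROI table as CSV, a run log, and a resolved
#' configuration copy stamped with its own MD5 hash and the seed. Rerunning
#' with an identical configuration reproduces identical artifacts. If
#' `config$table` names a cohort-level ROI table (CSV), the statistical
#' battery (Mann-Whitney comparisons, ROC ranking, marker correlations
#' where marker columns exist) and the ranked report are produced as well.
#'
#' @param config A named list overriding [defaultPipelineConfig()] entries,
#'   or the path of a YAML file with the same structure. `dwi`, `bval`,
#'   `bvec`, `roi` and `out` are required for the image stages; any missing
#'   input file fails before computation with the offending path.
#' @return Invisibly, a list with the fitted objects (`field`, `scalar`,
#'   `wmti`, `roiTable`) and, when cohort statistics ran, `comparisons`,
#'   `rocs`, `correlations`, `report`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultPipelineConfig(), config)
  if (is.null(cfg$out)) stop("config$out is required")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  logLines <- character()
  note <- function(...) {
    line <- paste0(...)
    logLines <<- c(logLines, line)
    message(line)
  }
  imageStage <- !is.null(cfg$dwi)
  for (nm in c(if (imageStage) c("dwi", "bval", "bvec"),
               if (!is.null(cfg$roi)) "roi",
               if (!is.null(cfg$cbf)) "cbf",
               if (!is.null(cfg$mask)) "mask",
               if (!is.null(cfg$table)) "table")) {
    if (!file.exists(cfg[[nm]]))
      stop("missing input: ", nm, " file not found at ", cfg[[nm]])
  }
  result <- list()
  roiTable <- NULL
  if (imageStage) {
    scheme <- readBvalBvec(cfg$bval, cfg$bvec)
    dwiImg <- RNifti::readNifti(cfg$dwi)
    dwi <- as.array(dwiImg)
    voxelSize <- RNifti::pixdim(dwiImg)[1:3]
    if (length(dim(dwi)) == 3L)  # singleton z dropped by the reader
      dim(dwi) <- c(dim(dwi)[1:2], 1L, dim(dwi)[3])
    roi <- if (!is.null(cfg$roi))
      ensure3d(round(as.array(RNifti::readNifti(cfg$roi)))) else NULL
    mask <- if (!is.null(cfg$mask))
      ensure3d(as.array(RNifti::readNifti(cfg$mask))) > 0 else NULL
    cbf <- if (!is.null(cfg$cbf))
      ensure3d(as.array(RNifti::readNifti(cfg$cbf)))
      else array(NA_real_, dim(dwi)[1:3])
    note("fit: ", nVolumes(scheme), " volumes on grid ",
         paste(dim(dwi)[1:3], collapse = "x"))
    field <- withCallingHandlers(
      fitVolume(dwi, scheme, mask = mask,
                weighting = cfg$fit$weighting, voxelSize = voxelSize),
      message = function(m) {
        logLines <<- c(logLines, conditionMessage(m)); invokeRestart("muffleMessage")
      })
    scalar <- scalarMaps(field, nSphere = cfg$metrics$nSphere,
                         nPerp = cfg$metrics$nPerp,
                         kaVariant = cfg$metrics$kaVariant)
    scalar <- withCallingHandlers(
      qcFilter(scalar, cfg$qc$lower, cfg$qc$upper),
      message = function(m) {
        logLines <<- c(logLines, conditionMessage(m)); invokeRestart("muffleMessage")
      })
    wmti <- withCallingHandlers(
      wmtiMaps(field, validKurtosis = scalar@validKurtosis,
               nSphere = cfg$metrics$nSphere),
      message = function(m) {
        logLines <<- c(logLines, conditionMessage(m)); invokeRestart("muffleMessage")
      })
    if (!is.null(roi)) {
      roiTable <- withCallingHandlers(
        roiMeans(scalar, wmti, cbf, roi, caseId = cfg$caseId),
        message = function(m) {
          logLines <<- c(logLines, conditionMessage(m)); invokeRestart("muffleMessage")
        })
    }
    writeNiftiMap(field@d, file.path(cfg$out, "tensor_d.nii.gz"))
    writeNiftiMap(field@w, file.path(cfg$out, "tensor_w.nii.gz"))
    writeNiftiMap(field@valid + 0, file.path(cfg$out, "valid.nii.gz"))
    for (nm in names(mapList(scalar)))
      writeNiftiMap(mapList(scalar)[[nm]],
                    file.path(cfg$out, paste0(tolower(nm), ".nii.gz")),
                    voxelSize = voxelSize)
    for (nm in names(mapList(wmti)))
      writeNiftiMap(mapList(wmti)[[nm]],
                    file.path(cfg$out, paste0(tolower(nm), ".nii.gz")),
                    voxelSize = voxelSize)
    if (!is.null(roiTable))
      utils::write.csv(roiTable, file.path(cfg$out, "roi_table.csv"),
                       row.names = FALSE)
    note("wrote maps for ", cfg$caseId)
    result <- c(result, list(field = field, scalar = scalar, wmti = wmti,
                             roiTable = roiTable))
  }
  if (!is.null(cfg$table)) {
    tab <- utils::read.csv(cfg$table, stringsAsFactors = FALSE)
    st <- cfg$stats
    comparisons <- do.call(rbind, lapply(st$pairs, function(pr)
      compareRois(tab, pr[1], pr[2], alpha = st$alphaCompare)))
    rocs <- do.call(rbind, lapply(st$pairs, function(pr)
      rocAnalysis(tab, pr[1], pr[2], nBoot = st$nBoot, seed = st$seed)))
    markers <- intersect(c("Ki67_LI", "Bcl2_EA", "CD133_EA"), names(tab))
    correlations <- NULL
    if (length(markers) > 0) {
      correlations <- do.call(rbind, lapply(1:3, function(z) {
        sub <- tab[tab$roi == z, markers, drop = FALSE]
        if (all(!is.finite(as.matrix(sub)))) return(NULL)
        markerCorrelations(tab, z, markers = markers,
                           alpha = st$alphaCorrelate, nBoot = st$nBoot,
                           seed = st$seed + z)
      }))
    }
    rep <- statReport(comparisons, rocs, correlations,
                      file = file.path(cfg$out, "report.md"))
    utils::write.csv(rep$ranking, file.path(cfg$out, "ranking.csv"),
                     row.names = FALSE)
    note("wrote statistics report (", length(st$pairs), " ROI pairs)")
    result <- c(result, list(comparisons = comparisons, rocs = rocs,
                             correlations = correlations, report = rep))
  }
  cfgPath <- file.path(cfg$out, "config_resolved.yaml")
  yaml::write_yaml(cfg, cfgPath)
  hash <- unname(tools::md5sum(cfgPath))
  writeLines(c(paste0("config_md5: ", hash),
               paste0("seed: ", cfg$stats$seed), logLines),
             file.path(cfg$out, "run.log"))
  invisible(result)
}

#' Write phantom outputs to disk in exchange formats
#'
#' Writes a [buildPhantom()] result as NIfTI-1 volumes (4-D DWI, CBF, zone
#' labels, ROI patches, one ground-truth map per parameter) plus FSL-style
#' `.bval`/`.bvec` files, ready to be consumed by [runPipeline()].
#'
#' @param phantom Result of [buildPhantom()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- phantom$spec@voxelSize
  writeNiftiMap(phantom$dwi, file.path(dir, "dwi.nii.gz"),
                voxelSize = c(vs, 1))
  writeNiftiMap(phantom$cbf, file.path(dir, "cbf.nii.gz"), voxelSize = vs)
  writeNiftiMap(phantom$labels + 0, file.path(dir, "labels.nii.gz"),
                voxelSize = vs)
  writeNiftiMap(phantom$roi + 0, file.path(dir, "roi.nii.gz"),
                voxelSize = vs)
  for (nm in names(phantom$truth))
    writeNiftiMap(phantom$truth[[nm]],
                  file.path(dir, paste0("truth_", tolower(nm), ".nii.gz")),
                  voxelSize = vs)
  writeBvalBvec(phantom$scheme, file.path(dir, "dwi.bval"),
                file.path(dir, "dwi.bvec"))
  invisible(dir)
}
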