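#' Per-ROI mean parameter values for one case
#'
#' Averages every quantitative map over the valid voxels of each ROI label:
#' MD/FA over tensor-valid voxels, kurtosis maps over QC-surviving voxels,
#' tract-integrity maps over their own validity masks (intra-axonal maps
#' and TORT over `validIntra`), CBF over all ROI voxels. A parameter whose
#' ROI retains zero valid voxels yields `NA` (and a message); a label
#' absent from the mask yields a warning and no row. Only these means enter
#' the downstream statistics.
#'
#' @param scalar A [ScalarMapSet-class].
#' @param wmti A [WMTIMapSet-class] on the same grid.
#' @param cbf 3-D CBF array (mL/100 g/min) on the same grid.
#' @param roi 3-D integer array of ROI labels 1-4 (0 = outside).
#' @param caseId Case identifier for the emitted rows.
#' @return data.frame with columns `case_id`, `roi`, `nVoxels`, and the 13
#'   parameters of [quantParamNames()].
#' @export
roiMeans <- function(scalar, wmti, cbf, roi, caseId = "case") {
  stopifnot(is(scalar, "ScalarMapSet"), is(wmti, "WMTIMapSet"))
  grid <- dim(scalar@md)
  stopifnot(identical(dim(cbf), grid), identical(dim(roi), grid))
  smaps <- mapList(scalar)
  wmaps <- mapList(wmti)
  validFor <- function(p) {
    switch(p,
           MD = , FA = scalar@validTensor,
           MK = , AK = , RK = , KA = scalar@validKurtosis,
           AWF = , AxEAD = , RadEAD = wmti@valid,
           AxIAD = , RadIAD = , TORT = wmti@validIntra,
           CBF = array(TRUE, grid))
  }
  mapFor <- function(p) {
    if (p %in% names(smaps)) smaps[[p]]
    else if (p %in% names(wmaps)) wmaps[[p]]
    else cbf
  }
  rows <- list()
  for (z in 1:4) {
    inroi <- roi == z
    if (!any(inroi)) {
      warning("missing ROI ", z, " in label mask; row omitted")
      next
    }
    row <- list(case_id = caseId, roi = z, nVoxels = sum(inroi))
    for (p in quantParamNames()) {
      sel <- inroi & validFor(p)
      m <- mapFor(p)[sel]
      m <- m[is.finite(m)]
      if (length(m) == 0L) {
        message("ROI ", z, ": no valid voxels for ", p, "; value missing")
        row[[p]] <- NA_real_
      } else row[[p]] <- mean(m)
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row,
                                               stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Exact two-sided Mann-Whitney by enumeration of all group-label
# assignments of the pooled sample (valid with ties). Returns U for x vs y
# and p = min(1, 2 * min(P(U <= u), P(U >= u))).
mannWhitneyExact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  uAll <- apply(combos, 2L, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  p <- min(1, 2 * min(mean(uAll <= uObs + eps), mean(uAll >= uObs - eps)))
  c(U = uObs, p = p)
}

#' Mann-Whitney zone comparisons across the cohort
#'
#' Two-sided Mann-Whitney test per parameter between two ROIs, each case
#' contributing one mean per ROI, treated as independent samples (matching
#' the reference analysis; statistically debatable for intra-patient ROI
#' pairs, see the package vignette). Exact enumeration of the permutation
#' distribution when both groups have at most `exactMax` cases; otherwise
#' the normal approximation with tie correction. The default comparisons
#' of the pipeline are the adjacent pairs 1-2, 2-3 and 3-4.
#'
#' @param table ROI table (from [roiMeans()] rows or [simulateCohort()]).
#' @param roiA,roiB ROI labels to compare.
#' @param params Parameter columns (default all 13 present).
#' @param alpha Significance threshold (default 0.001, the reference
#'   zone-comparison level).
#' @param exactMax Largest per-group size for exact enumeration.
#' @return data.frame: `parameter`, `roiA`, `roiB`, `U`, `p`, `nA`, `nB`,
#'   `significant`, `degenerate`.
#' @export
compareRois <- function(table, roiA, roiB, params = NULL, alpha = 0.001,
                        exactMax = 8L) {
  params <- resolveParams(table, params)
  out <- lapply(params, function(p) {
    x <- table[[p]][table$roi == roiA]
    y <- table[[p]][table$roi == roiB]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 3L || length(y) < 3L)
      stop("need at least 3 cases per group for ", p)
    degen <- length(unique(c(x, y))) == 1L
    if (degen) {
      u <- length(x) * length(y) / 2; pv <- 1
    } else if (length(x) <= exactMax && length(y) <= exactMax) {
      res <- mannWhitneyExact(x, y); u <- res[["U"]]; pv <- res[["p"]]
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE))
      u <- unname(wt$statistic); pv <- wt$p.value
    }
    data.frame(parameter = p, roiA = roiA, roiB = roiB, U = u, p = pv,
               nA = length(x), nB = length(y),
               significant = pv < alpha, degenerate = degen,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# AUC as the normalised concordant-pair count (ties count 1/2), computed
# via midranks; orientation NOT applied here.
aucConcordance <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos); n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Empirical ROC of group a vs group b for one parameter. Direction chosen
# so AUC >= 0.5; cutoff by Youden's J over midpoint thresholds, ties
# resolved toward higher specificity.
rocOne <- function(x, y, nBoot, alpha = 0.05) {
  degenerate <- length(unique(c(x, y))) == 1L
  auc <- aucConcordance(x, y)
  direction <- if (auc >= 0.5) "greater" else "less"
  if (direction == "less") auc <- 1 - auc
  xo <- if (direction == "greater") x else -x
  yo <- if (direction == "greater") y else -y
  vals <- sort(unique(c(xo, yo)))
  thr <- if (length(vals) > 1L) (vals[-1] + vals[-length(vals)]) / 2
         else vals
  sens <- vapply(thr, function(t) mean(xo >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(yo < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[which.max(spec[best])]
  cutoff <- thr[best]
  if (direction == "less") cutoff <- -cutoff
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0) {
    aucB <- vapply(seq_len(nBoot), function(i) {
      xb <- sample(x, replace = TRUE)
      yb <- sample(y, replace = TRUE)
      a <- aucConcordance(xb, yb)
      max(a, 1 - a)  # same orientation-free magnitude as the point estimate
    }, numeric(1))
    ci <- unname(stats::quantile(aucB, c(alpha / 2, 1 - alpha / 2),
                                 type = 7))
  }
  list(auc = auc, cutoff = cutoff, sensitivity = sens[best],
       specificity = spec[best], direction = direction,
       ciLower = ci[1], ciUpper = ci[2], degenerate = degenerate)
}

#' ROC analysis of zone discrimination, ranked by AUC
#'
#' Empirical ROC per parameter for one ROI pair, with orientation chosen so
#' AUC >= 0.5 (the sign of the comparison is recorded in `direction`),
#' cutoff at the maximum of Youden's J (ties broken toward higher
#' specificity), sensitivity/specificity at that cutoff, and a percentile
#' bootstrap confidence interval for the AUC obtained by resampling cases
#' within each group. Results are sorted by decreasing AUC, mirroring the
#' published ranking tables.
#'
#' @param table ROI table.
#' @param roiA,roiB ROI labels; `roiA` is the reference "positive" zone.
#' @param params Parameter columns (default all present).
#' @param nBoot Bootstrap replications (>= 200; default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param ciLevel Confidence level of the percentile interval.
#' @return data.frame: `parameter`, `roiA`, `roiB`, `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `ciLower`, `ciUpper`, `direction`,
#'   `nBoot`, `degenerate`, sorted by decreasing AUC.
#' @export
rocAnalysis <- function(table, roiA, roiB, params = NULL, nBoot = 2000L,
                        seed = 1L, ciLevel = 0.95) {
  if (nBoot != 0 && nBoot < 200L) stop("nBoot must be 0 or >= 200")
  params <- resolveParams(table, params)
  set.seed(seed)
  out <- lapply(params, function(p) {
    x <- table[[p]][table$roi == roiA]
    y <- table[[p]][table$roi == roiB]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) == 0L || length(y) == 0L)
      stop("empty group for ", p)
    r <- rocOne(x, y, nBoot, alpha = 1 - ciLevel)
    data.frame(parameter = p, roiA = roiA, roiB = roiB, auc = r$auc,
               cutoff = r$cutoff, sensitivity = r$sensitivity,
               specificity = r$specificity, ciLower = r$ciLower,
               ciUpper = r$ciUpper, direction = r$direction,
               nBoot = nBoot, degenerate = r$degenerate,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(-res$auc, res$parameter), , drop = FALSE]
}

#' Spearman correlations between imaging parameters and markers
#'
#' Spearman rank correlation of each parameter with each marker within one
#' ROI, with the tie-corrected asymptotic p-value and a percentile
#' bootstrap 95\% confidence interval (cases resampled). Pairs with fewer
#' than 5 complete observations are rejected; constant columns yield an
#' undefined correlation flagged `degenerate`.
#'
#' @param table ROI table containing marker columns.
#' @param roi ROI label to analyse.
#' @param markers Marker column names (default the ones present among
#'   `Ki67_LI`, `Bcl2_EA`, `CD133_EA`).
#' @param params Parameter columns (default all present).
#' @param alpha Significance threshold (default 0.05, the reference
#'   correlation level).
#' @param nBoot Bootstrap replications.
#' @param seed Integer seed.
#' @return data.frame: `parameter`, `roi`, `marker`, `rho`, `p`, `ciLower`,
#'   `ciUpper`, `n`, `significant`, `degenerate`.
#' @export
markerCorrelations <- function(table, roi, markers = NULL, params = NULL,
                               alpha = 0.05, nBoot = 2000L, seed = 1L) {
  params <- resolveParams(table, params)
  if (is.null(markers))
    markers <- intersect(c("Ki67_LI", "Bcl2_EA", "CD133_EA"), names(table))
  stopifnot(length(markers) > 0)
  set.seed(seed)
  sub <- table[table$roi == roi, , drop = FALSE]
  out <- list()
  for (mk in markers) {
    for (p in params) {
      ok <- is.finite(sub[[p]]) & is.finite(sub[[mk]])
      x <- sub[[p]][ok]; y <- sub[[mk]][ok]
      n <- length(x)
      if (n < 5L) stop("need at least 5 paired observations for ",
                       p, " vs ", mk)
      degen <- length(unique(x)) == 1L || length(unique(y)) == 1L
      if (degen) {
        rho <- NA_real_; pv <- NA_real_; ci <- c(NA_real_, NA_real_)
      } else {
        ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                               exact = FALSE))
        rho <- unname(ct$estimate); pv <- ct$p.value
        rb <- vapply(seq_len(nBoot), function(i) {
          ix <- sample.int(n, replace = TRUE)
          if (length(unique(x[ix])) == 1L || length(unique(y[ix])) == 1L)
            return(NA_real_)
          stats::cor(x[ix], y[ix], method = "spearman")
        }, numeric(1))
        ci <- unname(stats::quantile(rb, c(0.025, 0.975), na.rm = TRUE))
      }
      out[[length(out) + 1L]] <- data.frame(
        parameter = p, roi = roi, marker = mk, rho = rho, p = pv,
        ciLower = ci[1], ciUpper = ci[2], n = n,
        significant = !degen && pv < alpha, degenerate = degen,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Assemble the ranked summary report
#'
#' Combines comparison, ROC and correlation results into one deterministic
#' report: a table-shaped CSV block per ROI pair (parameters ordered by
#' decreasing AUC, with the Mann-Whitney p and significance flag joined in)
#' and an optional correlation block. Identical inputs give byte-identical
#' output.
#'
#' @param comparisons Output of [compareRois()] (rows for any pairs).
#' @param rocs Output of [rocAnalysis()].
#' @param correlations Optional output of [markerCorrelations()].
#' @param file Optional path; the markdown report is written there.
#' @return Invisibly, a list with `ranking` (merged data.frame) and
#'   `lines` (the report text).
#' @export
statReport <- function(comparisons, rocs, correlations = NULL,
                       file = NULL) {
  stopifnot(nrow(comparisons) > 0, nrow(rocs) > 0)
  merged <- merge(rocs, comparisons[, c("parameter", "roiA", "roiB", "U",
                                        "p", "significant")],
                  by = c("parameter", "roiA", "roiB"), all.x = TRUE)
  merged <- merged[order(merged$roiA, merged$roiB, -merged$auc,
                         merged$parameter), , drop = FALSE]
  rownames(merged) <- NULL
  lines <- c("# Zone discrimination report", "")
  for (key in unique(paste(merged$roiA, merged$roiB))) {
    pr <- strsplit(key, " ")[[1]]
    blk <- merged[merged$roiA == pr[1] & merged$roiB == pr[2], ]
    lines <- c(lines, sprintf("## ROI%s vs ROI%s", pr[1], pr[2]), "",
               "| parameter | AUC | cutoff | sens | spec | p (MW) | sig |",
               "|---|---|---|---|---|---|---|",
               sprintf("| %s | %.3f | %.3g | %.2f | %.2f | %.3g | %s |",
                       blk$parameter, blk$auc, blk$cutoff,
                       blk$sensitivity, blk$specificity, blk$p,
                       ifelse(is.na(blk$significant), "",
                              ifelse(blk$significant, "*", ""))),
               "")
  }
  if (!is.null(correlations) && nrow(correlations) > 0) {
    lines <- c(lines, "## Marker correlations", "",
               "| ROI | marker | parameter | rho | 95% CI | p | sig |",
               "|---|---|---|---|---|---|---|",
               sprintf("| %d | %s | %s | %.3f | [%.3f, %.3f] | %.3g | %s |",
                       correlations$roi, correlations$marker,
                       correlations$parameter, correlations$rho,
                       correlations$ciLower, correlations$ciUpper,
                       correlations$p,
                       ifelse(correlations$significant, "*", "")),
               "")
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(list(ranking = merged, lines = lines))
}

resolveParams <- function(table, params) {
  if (is.null(params)) params <- intersect(quantParamNames(), names(table))
  missing <- setdiff(params, names(table))
  if (length(missing) > 0)
    stop("parameters absent from table: ", paste(missing, collapse = ", "))
  params
}
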