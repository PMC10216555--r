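constMapSet <- function(grid, value, validK = NULL) {
  arr <- function(v) array(v, grid)
  vk <- if (is.null(validK)) arr(TRUE) else validK
  scalar <- new("ScalarMapSet", md = arr(value), fa = arr(0.5),
                mk = arr(value), ak = arr(value), rk = arr(value),
                ka = arr(0.1), validTensor = arr(TRUE), validKurtosis = vk,
                voxelSize = c(2.5, 2.5, 2.5))
  wmti <- new("WMTIMapSet", awf = arr(0.3), axEAD = arr(2),
              radEAD = arr(0.8), axIAD = arr(0.8), radIAD = arr(0),
              tort = arr(2.5), valid = vk, validIntra = vk,
              voxelSize = c(2.5, 2.5, 2.5))
  list(scalar = scalar, wmti = wmti)
}

test_that("ROI means average valid voxels and honour missingness contracts", {
  grid <- c(8L, 2L, 1L)
  roi <- array(0L, grid)
  roi[1:2, 1, 1] <- 1L; roi[3:4, 1, 1] <- 2L; roi[5:6, 1, 1] <- 3L
  ms <- constMapSet(grid, 0.7)
  cbf <- array(42, grid)
  expect_warning(tab <- roiMeans(ms$scalar, ms$wmti, cbf, roi, "c1"),
                 "missing ROI 4")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$MK, rep(0.7, 3))
  expect_equal(tab$CBF, rep(42, 3))

  # QC removed every voxel of ROI 1: kurtosis means missing, MD kept
  vk <- array(TRUE, grid); vk[1:2, 1, 1] <- FALSE
  ms2 <- constMapSet(grid, 0.7, validK = vk)
  suppressMessages(expect_warning(
    tab2 <- roiMeans(ms2$scalar, ms2$wmti, cbf, roi, "c1"), "missing ROI 4"))
  expect_true(is.na(tab2$MK[tab2$roi == 1]))
  expect_false(is.na(tab2$MD[tab2$roi == 1]))
})

test_that("exact Mann-Whitney enumeration matches the hand-derived example", {
  res <- gliomaDKI:::mannWhitneyExact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res["U"]), 0)
  expect_equal(unname(res["p"]), 0.1)  # 2/20 assignments as extreme
})

test_that("compareRois handles identical groups, ties, and both p-value paths", {
  tab <- data.frame(roi = rep(c(1, 2), each = 5),
                    MD = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5))
  res <- compareRois(tab, 1, 2, params = "MD")
  expect_equal(res$p, 1)
  tabD <- data.frame(roi = rep(c(1, 2), each = 4), MD = rep(7, 8))
  resD <- compareRois(tabD, 1, 2, params = "MD")
  expect_true(resD$degenerate)
  expect_equal(resD$p, 1)

  # exact enumeration agrees with the tie-free exact oracle (wilcox.test)
  set.seed(13)
  for (i in 1:10) {
    pool <- sample(1000, 13)  # distinct values, no ties
    x <- pool[1:6]; y <- pool[7:13]
    mine <- gliomaDKI:::mannWhitneyExact(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(unname(mine["U"]), unname(ref$statistic))
    expect_equal(unname(mine["p"]), ref$p.value, tolerance = 1e-12)
  }

  # large samples: normal approximation path equals wilcox.test
  set.seed(14)
  tabL <- data.frame(roi = rep(c(1, 2), each = 30),
                     MD = c(rnorm(30), rnorm(30, 0.5)))
  resL <- compareRois(tabL, 1, 2, params = "MD")
  ref <- stats::wilcox.test(tabL$MD[tabL$roi == 1], tabL$MD[tabL$roi == 2],
                            exact = FALSE, correct = TRUE)
  expect_equal(resL$p, ref$p.value)
})

test_that("AUC equals the brute-force concordant-pair count", {
  set.seed(17)
  for (i in 1:10) {
    n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
    x <- round(rnorm(n1, 1), 1); y <- round(rnorm(n2), 1)  # with ties
    brute <- mean(outer(x, y, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(gliomaDKI:::aucConcordance(x, y), brute,
                 tolerance = 1e-12)
  }
})

test_that("ROC orientation, Youden cutoff and separation limits behave", {
  tab <- data.frame(roi = rep(c(1, 2), each = 6),
                    MD = c(10, 11, 12, 13, 14, 15, 1, 2, 3, 4, 5, 6))
  r <- rocAnalysis(tab, 1, 2, params = "MD", nBoot = 200, seed = 1)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(r$cutoff > 6 && r$cutoff < 10)
  expect_lte(r$ciLower, r$ciUpper)

  # flipped orientation gives the same AUC with direction recorded
  tab$MDneg <- -tab$MD
  r2 <- rocAnalysis(tab, 1, 2, params = "MDneg", nBoot = 0, seed = 1)
  expect_equal(r2$auc, 1)
  expect_equal(r2$direction, "less")

  # monotone transform invariance of AUC
  tab$MDexp <- exp(tab$MD / 5)
  r3 <- rocAnalysis(tab, 1, 2, params = "MDexp", nBoot = 0, seed = 1)
  expect_equal(r3$auc, r$auc)

  # both groups one identical constant: flagged, AUC 1/2
  tabC <- data.frame(roi = rep(c(1, 2), each = 4), MD = rep(3, 8))
  rC <- rocAnalysis(tabC, 1, 2, params = "MD", nBoot = 0, seed = 1)
  expect_true(rC$degenerate)
  expect_equal(rC$auc, 0.5)
})

test_that("null groups give AUC near one half", {
  set.seed(19)
  tab <- data.frame(roi = rep(c(1, 2), each = 200), MD = rnorm(400))
  r <- rocAnalysis(tab, 1, 2, params = "MD", nBoot = 0, seed = 2)
  expect_gt(r$auc, 0.4)
  expect_lt(r$auc, 0.6)
})

test_that("ROC results agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:5) {
    x <- rnorm(20, 1); y <- rnorm(25)
    tab <- data.frame(roi = rep(c(1, 2), c(20, 25)), MD = c(x, y))
    mine <- rocAnalysis(tab, 1, 2, params = "MD", nBoot = 0, seed = 1)
    ref <- pROC::roc(response = rep(c(1, 0), c(20, 25)),
                     predictor = c(x, y), quiet = TRUE)
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    best <- pROC::coords(ref, "best", best.method = "youden",
                         transpose = FALSE)
    expect_equal(mine$cutoff, best$threshold, tolerance = 1e-9)
  }
})

test_that("Spearman correlations hit the monotone limits", {
  x <- c(1, 2, 3, 4, 5, 6)
  tab <- data.frame(roi = 1, MD = x, Ki67_LI = exp(x))
  res <- markerCorrelations(tab, 1, params = "MD", nBoot = 200, seed = 3)
  expect_equal(res$rho, 1)
  expect_lt(res$p, 0.05)
  tab$Ki67_LI <- -x^3
  res2 <- markerCorrelations(tab, 1, params = "MD", nBoot = 200, seed = 3)
  expect_equal(res2$rho, -1)
  tab$Ki67_LI <- rep(1, 6)
  res3 <- markerCorrelations(tab, 1, params = "MD", nBoot = 200, seed = 3)
  expect_true(res3$degenerate)
})

test_that("bootstrap CIs for rho have near-nominal coverage", {
  set.seed(29)
  trueRho <- 0.5
  r <- 2 * sin(pi * trueRho / 6)
  hits <- 0L
  nRep <- 200L
  for (i in seq_len(nRep)) {
    z1 <- rnorm(50); z2 <- r * z1 + sqrt(1 - r^2) * rnorm(50)
    tab <- data.frame(roi = 1, MD = z1, Ki67_LI = z2)
    res <- markerCorrelations(tab, 1, params = "MD", nBoot = 400,
                              seed = 1000 + i)
    if (res$ciLower <= trueRho && trueRho <= res$ciUpper) hits <- hits + 1L
  }
  expect_gte(hits / nRep, 0.90)
  expect_lte(hits / nRep, 0.98)
})

test_that("the report is deterministic and ranks parameters by AUC", {
  tab <- simulateCohort(cohortSpec(nCases = 20, seed = 41))
  cmp <- compareRois(tab, 1, 2)
  roc <- rocAnalysis(tab, 1, 2, nBoot = 200, seed = 5)
  corr <- markerCorrelations(tab, 1, params = c("CBF", "AWF"),
                             nBoot = 200, seed = 5)
  f1 <- tempfile(); f2 <- tempfile()
  r1 <- statReport(cmp, roc, corr, file = f1)
  r2 <- statReport(cmp, roc, corr, file = f2)
  expect_identical(readLines(f1), readLines(f2))
  aucs <- r1$ranking$auc
  expect_true(all(diff(aucs) <= 1e-12))
  # correlation-free report still renders
  r3 <- statReport(cmp, roc, NULL)
  expect_false(any(grepl("Marker correlations", r3$lines)))
})
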