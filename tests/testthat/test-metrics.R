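makeField <- function(tpList, valid = NULL) {
  n <- length(tpList)
  d <- array(NA_real_, c(n, 1, 1, 6))
  w <- array(NA_real_, c(n, 1, 1, 15))
  s0 <- array(1000, c(n, 1, 1))
  v <- array(TRUE, c(n, 1, 1))
  for (i in seq_len(n)) {
    d[i, 1, 1, ] <- tpList[[i]]$d6
    w[i, 1, 1, ] <- tpList[[i]]$w15
  }
  if (!is.null(valid)) v[] <- valid
  new("TensorField", d = d, w = w, s0 = s0, valid = v,
      voxelSize = c(2.5, 2.5, 2.5))
}

isoKurtosisPair <- function(md, k0) {
  list(d6 = c(md, md, md, 0, 0, 0),
       w15 = k0 * gliomaDKI:::w15SymOuter(diag(3)), md = md)
}

test_that("FA follows the eigenvalue formula", {
  tp <- list(d6 = c(2, 1, 1, 0, 0, 0), w15 = rep(0, 15), md = 4 / 3)
  sv <- gliomaDKI:::scalarValues(tp)
  expect_equal(unname(sv$values["FA"]), sqrt(1 / 6), tolerance = 1e-12)
  expect_equal(unname(sv$values["MD"]), 4 / 3, tolerance = 1e-12)
})

test_that("isotropic kurtosis collapses MK, AK, RK to K0 and KA to 0", {
  tp <- isoKurtosisPair(md = 1.2, k0 = 0.8)
  sv <- gliomaDKI:::scalarValues(tp)$values
  expect_equal(unname(sv[c("MK", "AK", "RK")]), rep(0.8, 3),
               tolerance = 1e-9)
  expect_equal(unname(sv["KA"]), 0, tolerance = 1e-9)
})

test_that("Gaussian voxels have zero kurtosis scalars", {
  tp <- list(d6 = c(1.5, 1.0, 0.7, 0.1, 0, 0), w15 = rep(0, 15))
  sv <- gliomaDKI:::scalarValues(tp)$values
  expect_equal(unname(sv[c("MK", "AK", "RK", "KA")]), rep(0, 4),
               tolerance = 1e-12)
})

test_that("MK over the fixed 250-set matches a dense Monte-Carlo average", {
  set.seed(5)
  mc <- sphereDirections(10000)  # deterministic dense oracle set
  for (i in 1:10) {
    tp <- wmtiForward(randomTissue())
    mk <- gliomaDKI:::scalarValues(tp)$values[["MK"]]
    mkMC <- mean(apparentValues(tp, mc)[, "K"])
    expect_lt(abs(mk - mkMC), 1e-3)
  }
})

test_that("scalar invariants are rotation invariant", {
  set.seed(9)
  for (i in 1:5) {
    tp <- wmtiForward(randomTissue())
    rot <- randomRotation()
    svA <- gliomaDKI:::scalarValues(tp)$values
    svB <- gliomaDKI:::scalarValues(rotateTensorPair(tp, rot))$values
    expect_equal(svA, svB, tolerance = 1e-6)
  }
})

test_that("the MK deletion rule removes exactly the strictly out-of-range voxels", {
  tps <- lapply(c(-0.1, 0.5, 3.2, 2.9, 0, 3), isoKurtosisPair, md = 1)
  field <- makeField(tps)
  maps <- scalarMaps(field)
  expect_equal(as.vector(maps@mk), c(-0.1, 0.5, 3.2, 2.9, 0, 3),
               tolerance = 1e-9)
  filtered <- suppressMessages(qcFilter(maps))
  expect_equal(as.vector(filtered@validKurtosis),
               c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE))  # 0 and 3 retained
  # MD/FA validity untouched
  expect_equal(as.vector(filtered@validTensor), rep(TRUE, 6))
  # all in range: mask unchanged
  ok <- scalarMaps(makeField(lapply(c(0.5, 1.2), isoKurtosisPair, md = 1)))
  expect_equal(suppressMessages(qcFilter(ok))@validKurtosis,
               ok@validKurtosis)
})

test_that("non-finite tensor components invalidate the voxel", {
  bad <- list(d6 = c(NA, 1, 1, 0, 0, 0), w15 = rep(0, 15))
  field <- makeField(list(bad, isoKurtosisPair(1, 1)))
  maps <- scalarMaps(field)
  expect_false(maps@validKurtosis[1, 1, 1])
  expect_true(maps@validKurtosis[2, 1, 1])
})
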