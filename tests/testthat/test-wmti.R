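dirs250 <- sphereDirections(250)

isoKPair <- function(md, k0) {
  list(d6 = c(md, md, md, 0, 0, 0),
       w15 = k0 * gliomaDKI:::w15SymOuter(diag(3)), md = md)
}

test_that("the reference voxel inverts to its generating parameters", {
  tp <- wmtiForward(tissueParams(f = 0.3, daAx = 0.8, deAx = 2.0,
                                 deRad = 0.8))
  res <- gliomaDKI:::wmtiVoxel(tp, dirs250)
  v <- res$values
  expect_equal(unname(v["AWF"]), 0.3, tolerance = 1e-3)
  expect_equal(unname(v["AxEAD"]), 2.0, tolerance = 1e-3)
  expect_equal(unname(v["RadEAD"]), 0.8, tolerance = 1e-3)
  expect_equal(unname(v["AxIAD"]), 0.8, tolerance = 1e-3)
  expect_equal(unname(v["TORT"]), 2.5, tolerance = 1e-3)
  expect_lt(abs(v["RadIAD"]), 1e-6)
})

test_that("awf follows Kmax/(Kmax+3): isotropic K = 1 gives awf 1/4", {
  res <- gliomaDKI:::wmtiVoxel(isoKPair(1.0, 1.0), dirs250)
  expect_equal(unname(res$values["AWF"]), 0.25, tolerance = 1e-9)
})

test_that("Gaussian voxels get awf 0, invalid intra maps, and EAD = D", {
  tp <- list(d6 = c(1.6, 0.9, 0.9, 0, 0, 0), w15 = rep(0, 15), md = 1.4 / 1)
  tp$md <- sum(tp$d6[1:3]) / 3
  res <- gliomaDKI:::wmtiVoxel(tp, dirs250)
  expect_equal(unname(res$values["AWF"]), 0, tolerance = 1e-12)
  expect_false(res$validIntra)
  expect_true(res$valid)
  expect_equal(unname(res$values["AxEAD"]), 1.6, tolerance = 1e-9)
  expect_equal(unname(res$values["RadEAD"]), 0.9, tolerance = 1e-9)
  expect_true(is.na(res$values["TORT"]))
})

test_that("forward-inverse round trip holds across the preset family", {
  set.seed(31)
  for (i in 1:25) {
    p <- randomTissue()
    res <- gliomaDKI:::wmtiVoxel(wmtiForward(p), dirs250)
    v <- res$values
    expect_equal(unname(v["AWF"]), p@f, tolerance = 1e-3)
    expect_equal(unname(v["AxEAD"]), p@deAx, tolerance = 1e-3)
    expect_equal(unname(v["RadEAD"]), p@deRad, tolerance = 1e-3)
    expect_equal(unname(v["AxIAD"]), p@daAx, tolerance = 2e-3)
    expect_equal(unname(v["TORT"]), p@deAx / p@deRad, tolerance = 5e-3)
    expect_gte(unname(v["TORT"]), 1 - 1e-9)  # de_ax >= de_rad presets
  }
})

test_that("awf increases strictly with the maximum apparent kurtosis", {
  ks <- c(0.2, 0.5, 1.0, 1.8, 2.5)
  awfs <- vapply(ks, function(k)
    gliomaDKI:::wmtiVoxel(isoKPair(1, k), dirs250)$values[["AWF"]],
    numeric(1))
  expect_true(all(diff(awfs) > 0))
  expect_equal(awfs, ks / (ks + 3), tolerance = 1e-9)
})

test_that("doubling the direction set barely moves awf", {
  set.seed(17)
  for (i in 1:5) {
    tp <- wmtiForward(randomTissue())
    a1 <- gliomaDKI:::wmtiVoxel(tp, sphereDirections(250))$values[["AWF"]]
    a2 <- gliomaDKI:::wmtiVoxel(tp, sphereDirections(500))$values[["AWF"]]
    expect_lt(abs(a1 - a2), 1e-3)
  }
})

test_that("wmtiMaps runs over a field and respects the kurtosis QC mask", {
  tpA <- wmtiForward(tissueParams(0.3, 0.8, 2.0, 0.8))
  tpB <- wmtiForward(tissueParams(0.4, 1.0, 2.0, 0.6))
  d <- array(NA_real_, c(2, 1, 1, 6)); w <- array(NA_real_, c(2, 1, 1, 15))
  d[1, 1, 1, ] <- tpA$d6; d[2, 1, 1, ] <- tpB$d6
  w[1, 1, 1, ] <- tpA$w15; w[2, 1, 1, ] <- tpB$w15
  field <- new("TensorField", d = d, w = w,
               s0 = array(1, c(2, 1, 1)), valid = array(TRUE, c(2, 1, 1)),
               voxelSize = c(2.5, 2.5, 2.5))
  qcMask <- array(c(TRUE, FALSE), c(2, 1, 1))
  wm <- wmtiMaps(field, validKurtosis = qcMask)
  expect_true(wm@valid[1, 1, 1])
  expect_false(wm@valid[2, 1, 1])  # QC-deleted voxel skipped
  expect_equal(wm@awf[1, 1, 1], 0.3, tolerance = 1e-3)
})
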