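test_that("single-compartment and identical-compartment voxels have zero kurtosis", {
  p0 <- tissueParams(f = 0, daAx = 0.8, deAx = 2.0, deRad = 0.8)
  expect_true(all(abs(wmtiForward(p0)$w15) < 1e-12))
  pe <- tissueParams(f = 0.5, daAx = 2.0, deAx = 2.0, deRad = 2.0,
                     radIad = 2.0)
  expect_true(all(abs(wmtiForward(pe)$w15) < 1e-12))
  expect_error(tissueParams(f = 1.2, daAx = 1, deAx = 2, deRad = 1),
               "invalid fraction")
})

test_that("two-compartment projections match the mixture-cumulant formulas", {
  p <- tissueParams(f = 0.3, daAx = 0.8, deAx = 2.0, deRad = 0.8)
  tp <- wmtiForward(p)
  along <- apparentValues(tp, c(1, 0, 0))
  expect_equal(along[["D"]], 0.3 * 0.8 + 0.7 * 2.0, tolerance = 1e-12)
  kTrue <- 3 * 0.3 * 0.7 * (0.8 - 2.0)^2 / 1.64^2
  expect_equal(along[["K"]], kTrue, tolerance = 1e-12)
  # the same identity must hold along arbitrary directions
  set.seed(42)
  for (i in 1:10) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    da <- gliomaDKI:::axisymmetricTensor(0.8, 0, c(1, 0, 0))
    de <- gliomaDKI:::axisymmetricTensor(2.0, 0.8, c(1, 0, 0))
    dan <- drop(t(n) %*% da %*% n)
    den <- drop(t(n) %*% de %*% n)
    dn <- 0.3 * dan + 0.7 * den
    av <- apparentValues(tp, n)
    expect_equal(av[["D"]], dn, tolerance = 1e-12)
    expect_equal(av[["K"]], 3 * 0.3 * 0.7 * (dan - den)^2 / dn^2,
                 tolerance = 1e-10)
  }
})

test_that("kurtosis agrees with the numerical cumulant expansion of the bi-exponential", {
  # independent oracle: ln of the two-compartment signal expanded at small b
  p <- tissueParams(f = 0.3, daAx = 0.8, deAx = 2.0, deRad = 0.8)
  tp <- wmtiForward(p)
  n <- c(1, 0, 0)
  da <- 0.8; de <- 2.0; f <- 0.3
  biexp <- function(b) log(f * exp(-b * da) + (1 - f) * exp(-b * de))
  h <- 1e-3
  d2 <- (biexp(2 * h) - 2 * biexp(h) + biexp(0)) / h^2
  d1 <- (biexp(h) - biexp(0)) / h
  dApp <- -d1 + h / 2 * d2  # first cumulant corrected to O(h^2)
  kApp <- 3 * d2 / dApp^2   # K = 3 * c2 / D^2 with c2 the second cumulant
  av <- apparentValues(tp, n)
  expect_equal(av[["D"]], dApp, tolerance = 1e-4)
  expect_equal(av[["K"]], kApp, tolerance = 1e-3)
})

test_that("forward signal honours the mono-exponential and baseline limits", {
  iso <- list(d6 = c(1, 1, 1, 0, 0, 0), w15 = rep(0, 15), md = 1)
  s <- makeScheme(15, c(0, 1000, 2500))
  sig <- forwardSignal(iso, s, s0 = 1000)
  expect_equal(sig[1], 1000)                     # b = 0 baseline
  b1 <- which(bvalues(s) == 1000)
  expect_equal(unname(sig[b1]), rep(1000 * exp(-1), length(b1)),
               tolerance = 1e-12)
  bad <- s
  bad@bvalues[2] <- -5
  expect_error(forwardSignal(iso, bad), "invalid b-factor")
})

test_that("small-b log-slope of the forward signal recovers D(n)", {
  set.seed(7)
  tp <- wmtiForward(randomTissue())
  n <- rnorm(3); n <- n / sqrt(sum(n^2))
  h <- 1e-3  # s/mm^2: essentially the b -> 0 slope
  sch <- new("AcquisitionScheme",
             bvalues = c(0, rep(c(h, 2 * h), each = 15)),
             bvectors = matrix(n, 3, 31))
  sig <- forwardSignal(tp, sch, s0 = 1)
  dHat <- -(log(sig[2]) - log(sig[1])) / (h / 1000)
  expect_equal(dHat, unname(apparentValues(tp, n)[["D"]]),
               tolerance = 1e-6)
})
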