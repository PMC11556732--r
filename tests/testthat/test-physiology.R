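test_that("rate extraction is exact on a noiseless linear trace", {
  tm <- seq(0, 30, by = 0.25)
  tr <- OxygenTrace(tm, 250 - 0.5 * tm)
  est <- extractRate(tr)
  expect_equal(est$slope, -0.5, tolerance = 1e-10)
  expect_equal(unname(est$window), c(1, length(tm)))
  const <- OxygenTrace(tm, rep(250, length(tm)))
  ce <- extractRate(const)
  expect_equal(ce$slope, 0)
  expect_true(ce$degenerate)
  expect_error(extractRate(OxygenTrace(1:5, 5:1)), "at least 10")
})

test_that("equilibration artifacts are excluded from the fitted window", {
  errs <- vapply(1:20, function(s) {
    tr <- simulateOxygenTrace(-0.5, noiseSd = 0.3,
                              equilibrationFraction = 0.2,
                              equilibrationAmp = 5, seed = 900 + s)
    est <- extractRate(tr, stride = 2L)
    abs(est$slope - (-0.5)) / 0.5
  }, 0)
  expect_lt(mean(errs), 0.05)
})

test_that("rate normalization follows the blank/volume/count arithmetic", {
  out <- normalizeRate(-0.5, -0.1, 80e-6, 6)
  expect_equal(out$perIndividual, -0.4 * 80e-6 / 6 * 1e3, tolerance = 1e-12)
  expect_equal(normalizeRate(-0.3, -0.3, 80e-6, 6)$perIndividual, 0)
  # linear in (raw - blank); doubling individuals halves the rate
  expect_equal(normalizeRate(-0.9, -0.1, 80e-6, 12)$perIndividual,
               normalizeRate(-0.5, -0.1, 80e-6, 6)$perIndividual,
               tolerance = 1e-12)
  sz <- normalizeRate(-0.5, -0.1, 80e-6, 6, meanSizeMm3 = 0.11)
  expect_equal(sz$sizeNormalized, sz$perIndividual / 0.11)
  expect_error(normalizeRate(-0.5, -0.1, 80e-6, 0), "nIndividuals")
})

test_that("gross photosynthesis and P:R follow their definitions", {
  m <- photosynthesisMetrics(1, 1)
  expect_equal(m$grossP, 2); expect_equal(m$pToR, 2)
  m0 <- photosynthesisMetrics(0, 0.8)
  expect_equal(m0$grossP, 0.8); expect_equal(m0$pToR, 1)
  mneg <- photosynthesisMetrics(-0.8, 0.8)
  expect_equal(mneg$grossP, 0); expect_equal(mneg$pToR, 0)
  expect_warning(photosynthesisMetrics(1, 0), "undefined")
})

test_that("scalar physiology formulas match hand arithmetic", {
  ch <- chlorophyll(0.1, 0.05)
  expect_equal(ch$chlA, 1.9024, tolerance = 1e-4)
  expect_equal(ch$chlC2, 1.6978, tolerance = 1e-4)
  expect_equal(ch$total, ch$chlA + ch$chlC2)
  expect_error(chlorophyll(-0.1, 0.05), "non-negative")

  expect_equal(larvalVolume(0.2, 0.1), 2.0944e-3, tolerance = 1e-4)
  expect_equal(larvalVolume(0.01, 0.01), 5.236e-7, tolerance = 1e-4)
  expect_equal(larvalVolume(0.4, 0.2), 8 * larvalVolume(0.2, 0.1),
               tolerance = 1e-12)
  expect_error(larvalVolume(0, 0.1), "positive")

  expect_equal(settlementProportion(11, 100), 0.11)
  expect_equal(settlementProportion(0, 100), 0)
  expect_error(settlementProportion(101, 100), "nStart")
  expect_equal(survivalDensity(rep(25, 6), 25), 1)
})

test_that("physiology calculators agree with independent evaluations at random inputs", {
  set.seed(91)
  for (rep in 1:20) {
    e663 <- runif(1, 0, 1); e630 <- runif(1, 0, 1)
    ch <- chlorophyll(e663, e630)
    expect_equal(ch$chlA, (11.43 * e663 - 0.64 * e630) / 0.584,
                 tolerance = 1e-12)
    expect_equal(ch$chlC2, (27.09 * e630 - 3.63 * e663) / 0.584,
                 tolerance = 1e-12)
    L <- runif(1, 0.05, 0.5); W <- runif(1, 0.05, 0.5)
    expect_equal(larvalVolume(L, W), 4 / 3 * pi * (W / 2) * (L / 2)^2,
                 tolerance = 1e-12)
    np <- runif(1, -1, 2); r <- runif(1, 0.1, 2)
    pm <- photosynthesisMetrics(np, r)
    expect_equal(pm$grossP, np + r, tolerance = 1e-12)
    expect_equal(pm$pToR, (np + r) / r, tolerance = 1e-12)
    raw <- runif(1, -1, 0); blank <- runif(1, -0.2, 0)
    vol <- runif(1, 5e-5, 2e-4); k <- sample(1:10, 1)
    expect_equal(normalizeRate(raw, blank, vol, k)$perIndividual,
                 (raw - blank) * vol / k * 1000, tolerance = 1e-12)
  }
})
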