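# Speed decoding and Poiseuille flow mapping.

test_that("unit constants fall out of dimensional analysis", {
  # mm/s * um^2 -> mL/min conversion
  expect_equal(deriveFlowConstant(), 6e-8, tolerance = 1e-12)
  # 8-bit full scale over 0-100 mm/s
  expect_equal(deriveGreyDivisor(), 2.55, tolerance = 1e-15)
  expect_error(flowModelParams(greyDivisor = 2.5), "must equal")
})

test_that("speed decoding maps intensities onto 0-100 mm/s", {
  img <- intensityMap(matrix(c(0L, 51L, 102L, 255L), 2, 2), "speed")
  sm <- decodeSpeed(img)
  expect_equal(as.vector(mapValues(sm)), c(0, 20, 40, 100))
  sc <- horizontalVesselScene(gridPx = 64)
  expect_error(decodeSpeed(renderDirectionalMap(sc)), "speed map")
})

test_that("scalar flow follows Q = v * pi * r^2 * K", {
  expect_equal(flowRate(1, 2), pi * 6e-8, tolerance = 1e-12)
  expect_equal(flowRate(0, 20), 0)
  expect_equal(flowRate(10, 20), 10 * pi * 100 * 6e-8, tolerance = 1e-12)
  expect_error(flowRate(-1, 10), ">= 0")
  # linear in v, quadratic in diameter
  expect_equal(flowRate(8, 14), 4 * flowRate(2, 14))
  expect_equal(flowRate(3, 28), 4 * flowRate(3, 14))
})

test_that("uniform phantom vessels give exact interior per-pixel flow", {
  sc <- horizontalVesselScene(widthUm = 30, velocityMmS = 20, gridPx = 128)
  mask <- binarize(renderDensityMap(sc))
  tm <- applyReliabilityFloor(localThickness(mask), 5)
  sm <- decodeSpeed(renderSpeedMap(sc))
  fm <- flowRateMap(sm, tm, useFloor = TRUE)
  # interior pixels: decoded v and recovered d are constant, Q exact
  vDec <- 51 / 2.55 # round(20 * 2.55) = 51
  interior <- mapValues(tm)[64, 40:90]
  dRec <- as.numeric(names(sort(table(interior), decreasing = TRUE))[1])
  expectQ <- vDec * pi * (dRec / 2)^2 * 6e-8
  got <- mapValues(fm)[64, 40:90][interior == dRec]
  expect_equal(got, rep(expectQ, length(got)), tolerance = 1e-12)
  # zero speed -> zero flow
  sc0 <- horizontalVesselScene(velocityMmS = 0, gridPx = 64)
  fm0 <- flowRateMap(decodeSpeed(renderSpeedMap(sc0)),
                     localThickness(binarize(renderDensityMap(sc0))))
  expect_true(all(mapValues(fm0) == 0))
})

test_that("regional CBF is the pixel mean over eligible vessel pixels", {
  q <- matrix(0, 40, 40)
  q[5:10, ] <- 2e-6
  fm <- new("FlowMap", values = q, pixelSizeUm = 2)
  mask <- binaryMask(q > 0)
  rs <- fullCortexRegions(40)
  expect_equal(regionalCbf(fm, mask, rs, "cortex"), 2e-6)
  # all-region average is diluted by off-vessel zeros
  expect_equal(regionalCbf(fm, mask, rs, "cortex", domain = "all"),
               2e-6 * sum(q > 0) / 1600)
  none <- binaryMask(matrix(FALSE, 40, 40))
  expect_error(regionalCbf(fm, none, rs, "cortex"), "no eligible")
  # two vessels with known Q and pixel counts: pixel-weighted mean
  q2 <- matrix(0, 40, 40); q2[1:4, ] <- 1e-6; q2[30:35, ] <- 4e-6
  fm2 <- new("FlowMap", values = q2, pixelSizeUm = 2)
  n1 <- 4 * 40; n2 <- 6 * 40
  expect_equal(regionalCbf(fm2, binaryMask(q2 > 0), rs, "cortex"),
               (n1 * 1e-6 + n2 * 4e-6) / (n1 + n2))
})

test_that("mixed phantom flow agrees with recomputation from ground truth", {
  mk <- function(y, w, v) vesselSpec(c(60, y), c(452, y), widthUm = w,
                                     velocityMmS = v)
  sc <- makeScene(list(mk(80, 16, 10), mk(240, 24, 30), mk(400, 32, 50)),
                  c(256, 256))
  mask <- binarize(renderDensityMap(sc))
  tm <- applyReliabilityFloor(localThickness(mask), 5)
  fm <- flowRateMap(decodeSpeed(renderSpeedMap(sc)), tm)
  masks <- sceneVesselMasks(sc)
  for (i in 1:3) {
    vs <- sc@vessels[[i]]
    vDec <- round(vs@velocityMmS * 2.55) / 2.55
    # regional mean against analytic truth, edge pixels dominate the error
    rows <- which(masks[[i]], arr.ind = TRUE)[, 1]
    sel <- masks[[i]]
    meanQ <- mean(mapValues(fm)[sel])
    analytic <- vDec * pi * (vs@widthUm / 2)^2 * 6e-8
    expect_equal(meanQ, analytic, tolerance = 0.12)
  }
})

test_that("speed and flow histograms are normalized point/two-point masses", {
  mk <- function(y, v) vesselSpec(c(28, y), c(228, y), widthUm = 20,
                                  velocityMmS = v)
  sc <- makeScene(list(mk(60, 10), mk(180, 40)), c(128, 128))
  mask <- binarize(renderDensityMap(sc))
  rs <- fullCortexRegions(128)
  sm <- decodeSpeed(renderSpeedMap(sc))
  h <- speedDistribution(sm, mask, rs, "cortex", binWidthMmS = 2)
  expect_equal(sum(h$relFreq), 1, tolerance = 1e-9)
  m10 <- sum(h$relFreq[h$binLower >= 8 & h$binLower < 12])
  m40 <- sum(h$relFreq[h$binLower >= 38 & h$binLower < 42])
  expect_equal(m10 + m40, 1, tolerance = 1e-9)
  expect_equal(m10, 0.5, tolerance = 0.03) # equal-area vessels
  tm <- applyReliabilityFloor(localThickness(mask), 5)
  fh <- flowDistribution(flowRateMap(sm, tm), mask, rs, "cortex")
  expect_equal(sum(fh$relFreq), 1, tolerance = 1e-9)
  expect_true(all(diff(fh$binLower) > 0))
})
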