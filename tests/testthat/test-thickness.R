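# Local thickness: digitization rule cases, oracle equivalence, reliability
# floor, distributions.

test_that("canonical shapes get the expected inscribed-circle diameters", {
  # single isolated pixel: only the unit circle fits -> 1 px = 2 um
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_equal(mapValues(localThickness(binaryMask(m, 2)))[5, 5], 2)
  # 1-px-wide line: 1 px everywhere on the line
  m <- matrix(FALSE, 9, 30); m[5, 3:28] <- TRUE
  tl <- mapValues(localThickness(binaryMask(m, 2)))
  expect_true(all(tl[5, 3:28] == 2))
  # 5-px-wide strip: 5 px (10 um) at interior centre-line pixels
  m <- matrix(FALSE, 21, 40); m[9:13, 3:38] <- TRUE
  ts <- mapValues(localThickness(binaryMask(m, 2)))
  expect_true(all(ts[11, 8:33] == 10))
  # filled digital disk of radius R: centre diameter within 1 px of 2R
  for (R in c(4, 7, 11)) {
    n <- 2 * R + 5
    c0 <- (n + 1) / 2
    md <- outer(seq_len(n) - c0, seq_len(n) - c0,
                function(a, b) a^2 + b^2 <= R^2)
    td <- mapValues(localThickness(binaryMask(md, 1)))
    expect_lte(abs(td[c0, c0] - 2 * R), 1)
  }
})

test_that("empty masks warn and produce an all-zero map", {
  expect_warning(tm <- localThickness(binaryMask(matrix(FALSE, 5, 5))),
                 "empty mask")
  expect_true(all(mapValues(tm) == 0))
})

test_that("fast path equals the brute-force oracle on random masks", {
  set.seed(101)
  for (i in 1:40) {
    m <- randomBlobMask(sample(12:48, 1), sample(12:48, 1), sample(2:6, 1))
    if (!any(m)) next
    bm <- binaryMask(m, 2)
    expect_identical(mapValues(localThickness(bm)),
                     mapValues(thicknessOracle(bm)))
  }
})

test_that("the oracle refuses masks beyond its exhaustive-search guard", {
  expect_error(thicknessOracle(binaryMask(matrix(TRUE, 80, 80))), "guard")
})

test_that("dilation never decreases thickness; calibration scales linearly", {
  set.seed(21)
  for (i in 1:10) {
    m <- randomBlobMask(40, 40)
    if (!any(m)) next
    t1 <- mapValues(localThickness(binaryMask(m, 2)))
    grown <- m
    grown[-1, ] <- grown[-1, ] | m[-nrow(m), ] # shift-union dilation
    t2 <- mapValues(localThickness(binaryMask(grown, 2)))
    expect_true(all(t2 >= t1))
    t5 <- mapValues(localThickness(binaryMask(m, 5)))
    expect_equal(t5, t1 / 2 * 5)
  }
})

test_that("straight phantom vessels recover their width within one pixel", {
  for (w in c(10, 18, 26, 34, 42, 50)) {
    sc <- horizontalVesselScene(widthUm = w, gridPx = 128)
    tm <- localThickness(binarize(renderDensityMap(sc)))
    v <- mapValues(tm)
    interior <- v[64, 40:90] # away from the end caps
    expect_lte(abs(median(interior) - w), 2)
  }
})

test_that("the reliability floor flags small diameters without deleting them", {
  small <- matrix(FALSE, 20, 30); small[10:11, 3:28] <- TRUE # 2 px = 4 um
  tm <- applyReliabilityFloor(localThickness(binaryMask(small, 2)), 5)
  expect_true(all(tm@flagged[mapValues(tm) > 0]))
  expect_true(all(mapValues(tm)[small] > 0)) # values retained
  wide <- matrix(FALSE, 30, 30); wide[8:22, 3:28] <- TRUE # 15 px = 30 um
  tw <- applyReliabilityFloor(localThickness(binaryMask(wide, 2)), 5)
  # interior is far above the floor; only the strip-end corners, where no
  # large circle fits, are legitimately flagged
  expect_false(any(tw@flagged[, 10:20]))
  expect_lt(mean(tw@flagged[wide]), 0.05)
})

test_that("flagged area fraction matches the ground-truth share of thin vessels", {
  mk <- function(y, w) vesselSpec(c(60, y), c(452, y), widthUm = w,
                                  velocityMmS = 5)
  sc <- makeScene(list(mk(60, 4), mk(160, 8), mk(280, 12), mk(400, 20)),
                  c(256, 256))
  tm <- applyReliabilityFloor(localThickness(sceneMask(sc)), 5)
  masks <- sceneVesselMasks(sc)
  thinPx <- sum(masks[[1]] | masks[[2]])
  totPx <- sum(mapValues(sceneMask(sc)))
  flaggedFrac <- sum(tm@flagged) / totPx
  expect_equal(flaggedFrac, thinPx / totPx, tolerance = 0.05)
})

test_that("diameter distributions are normalized with modes at vessel widths", {
  sc <- horizontalVesselScene(widthUm = 20, gridPx = 128)
  rs <- fullCortexRegions(128)
  tm <- applyReliabilityFloor(localThickness(binarize(renderDensityMap(sc))), 5)
  h <- diameterDistribution(tm, rs, "cortex", binWidthUm = 2)
  expect_equal(sum(h$relFreq), 1, tolerance = 1e-9)
  expect_true(all(diff(h$binLower) > 0))
  mode <- h$binLower[which.max(h$relFreq)]
  expect_true(mode <= 20 && 20 < mode + 4)
  # two equal-capsule-area vessels -> two equal masses (within rasterization)
  a1 <- 250 * 12 + pi * 6^2 # 12 um x 250 um capsule
  len30 <- (a1 - pi * 15^2) / 30 # 30 um capsule with the same area
  sc2 <- makeScene(list(
    vesselSpec(c(28, 80), c(278, 80), widthUm = 12, velocityMmS = 5),
    vesselSpec(c(100, 220), c(100 + len30, 220), widthUm = 30,
               velocityMmS = 5)), c(160, 160))
  tm2 <- applyReliabilityFloor(localThickness(sceneMask(sc2)), 5)
  h2 <- diameterDistribution(tm2, fullCortexRegions(160), "cortex",
                             binWidthUm = 2)
  f12 <- sum(h2$relFreq[h2$binLower >= 8 & h2$binLower < 16])
  f30 <- sum(h2$relFreq[h2$binLower >= 24 & h2$binLower < 34])
  expect_equal(f12 / (f12 + f30), 0.5, tolerance = 0.05)
  # all-flagged region errors
  thin <- matrix(FALSE, 20, 30); thin[10, 3:28] <- TRUE
  tmThin <- applyReliabilityFloor(localThickness(binaryMask(thin, 2)), 5)
  rsThin <- makeRegionSet(c(20, 30), list(cortex = c(1, 20)))
  expect_error(diameterDistribution(tmThin, rsThin, "cortex"), "no eligible")
})
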