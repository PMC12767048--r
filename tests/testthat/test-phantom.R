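# Phantom generator: geometry, rendering, determinism, ground-truth
# bookkeeping.

test_that("scene construction validates geometry and rejects empty specs", {
  expect_error(makeScene(list(), c(64, 64)), "nonempty")
  # capsule reaching outside the grid
  v <- vesselSpec(c(20, 64), c(200, 64), widthUm = 30, velocityMmS = 5)
  expect_error(makeScene(list(v), gridShape = c(64, 64)), "outside the grid")
  # same vessel fits a larger grid
  expect_s4_class(makeScene(list(v), gridShape = c(64, 120)), "PhantomScene")
})

test_that("rasterized capsule area matches the analytic footprint", {
  # width an odd number of pixels so the on-lattice centerline rasterizes
  # to the exact strip height
  sc <- horizontalVesselScene(widthUm = 22, gridPx = 256)
  m <- mapValues(sceneMask(sc))
  lengthUm <- 512 - 2 * 60
  analytic <- (lengthUm * 22 + pi * 11^2) / 4 # px at 2 um/px
  expect_lt(abs(sum(m) - analytic) / analytic, 0.02)
})

test_that("cohort generation is deterministic for a fixed seed", {
  p <- smallCohortParams()
  a <- simulateCohort(p, seed = 7L)
  b <- simulateCohort(p, seed = 7L)
  expect_identical(mapValues(a$animals[[1]]$density),
                   mapValues(b$animals[[1]]$density))
  expect_identical(mapValues(a$animals[[3]]$speed),
                   mapValues(b$animals[[3]]$speed))
  expect_identical(a$animals[[2]]$trace@samples, b$animals[[2]]$trace@samples)
  expect_identical(a$truth, b$truth)
  d <- simulateCohort(p, seed = 8L)
  expect_false(identical(mapValues(a$animals[[1]]$density),
                         mapValues(d$animals[[1]]$density)))
})

test_that("binarized density render reproduces the rasterized union mask", {
  set.seed(5)
  vessels <- lapply(1:8, function(i) {
    ang <- runif(1, 0, pi); len <- runif(1, 60, 140)
    cx <- runif(1, 120, 392); cy <- runif(1, 120, 392)
    vesselSpec(c(cx, cy) - c(cos(ang), sin(ang)) * len / 2,
               c(cx, cy) + c(cos(ang), sin(ang)) * len / 2,
               widthUm = runif(1, 8, 30), velocityMmS = runif(1, 2, 40))
  })
  sc <- makeScene(vessels, c(256, 256))
  for (style in c("uniform", "speckle")) {
    dm <- renderDensityMap(sc, style)
    expect_true(all(mapValues(dm)[!mapValues(sceneMask(sc))] == 0L))
    expect_identical(mapValues(binarize(dm)), mapValues(sceneMask(sc)))
  }
})

test_that("speed render encodes round(v * 2.55) and round-trips within a step", {
  for (case in list(c(100, 255), c(0, 0), c(40, 102), c(20, 51))) {
    sc <- horizontalVesselScene(velocityMmS = case[1])
    sm <- renderSpeedMap(sc)
    on <- mapValues(sm)[mapValues(sceneMask(sc))]
    expect_true(all(on == case[2]))
    decoded <- unique(mapValues(decodeSpeed(sm))[mapValues(sceneMask(sc))])
    expect_lt(abs(decoded - case[1]), 100 / 255)
  }
})

test_that("directional render colors by flow direction with known pixel ratio", {
  mk <- function(y, dir) vesselSpec(c(60, y), c(452, y), widthUm = 16,
                                    velocityMmS = 5, direction = dir)
  sc <- makeScene(list(mk(80, "descending"), mk(180, "descending"),
                       mk(280, "descending"), mk(380, "ascending")),
                  c(256, 256))
  rgbArr <- mapValues(renderDirectionalMap(sc))
  red <- sum(rgbArr[, , 1] == 255L)
  blue <- sum(rgbArr[, , 3] == 255L)
  expect_equal(red / blue, 3.0)
  expect_equal(red + blue, sum(mapValues(sceneMask(sc))))
})

test_that("band region layouts partition the grid; bad layouts error", {
  rs <- makeRegionSet(c(300, 300), list(cortex = c(1, 100),
    hippocampus = c(101, 200), white_matter = c(201, 300)))
  counts <- vapply(c("cortex", "hippocampus", "white_matter"),
                   function(nm) sum(regionMask(rs, nm)), 0)
  expect_true(all(counts == 100 * 300))
  expect_equal(sum(regionMask(rs, "whole_brain")), sum(counts))
  # whole_brain superset of every region
  for (nm in names(counts))
    expect_true(all(regionMask(rs, "whole_brain")[regionMask(rs, nm)]))
  expect_error(makeRegionSet(c(300, 300), list(cortex = c(1, 301))), "outside")
  expect_error(makeRegionSet(c(300, 300),
    list(cortex = c(1, 100), hippocampus = c(50, 200))), "overlaps")
  expect_error(makeRegionSet(c(300, 300),
    list(whole_brain = c(1, 300))), "implicit")
})

test_that("simulated NVC traces hit the programmed amplitude and latency", {
  sch <- stimSchedule()
  flat <- simulateNvcTrace(hrfParams(amplitudePct = 0, noiseSdPct = 0), sch)
  expect_true(all(flat@samples == 100))
  tr <- simulateNvcTrace(hrfParams(amplitudePct = 20, latencyS = 5,
                                   noiseSdPct = 0), sch)
  trial1 <- tr@samples[1:450]
  expect_equal(max(trial1), 120, tolerance = 1e-6)
  # peak at 5 s after the 30 s onset: sample index 175 (t = 35 s)
  expect_equal(which.max(trial1) * 0.2, 35)
})

test_that("noisy per-trial peak estimates recover the true amplitude", {
  tr <- simulateNvcTrace(hrfParams(amplitudePct = 20, latencyS = 5,
                                   noiseSdPct = 2), stimSchedule(), seed = 3L)
  trials <- lapply(segmentTrials(tr), baselineNormalize)
  peaks <- vapply(trials, function(t) trialMetrics(t)$peakPct, 0)
  # the window-max estimator is upward-biased under noise; its sampling
  # distribution (Monte-Carlo over noise seeds) is mean 22.9, sd 0.45
  expect_gt(mean(peaks), 20)
  expect_lt(abs(mean(peaks) - 22.9), 2)
})

test_that("aged multipliers shape the cohort ground truth as programmed", {
  p <- cohortParams(nYoung = 4L, nAged = 4L, gridShape = c(150L, 150L))
  co <- simulateCohort(p, seed = 2L)
  tr <- co$truth
  young <- tr[tr$group == "young", ]; aged <- tr[tr$group == "aged", ]
  # coverage and width scale by 0.8, hippocampal velocity by 0.7 (by
  # construction up to the 5% between-animal lognormal jitter)
  expect_equal(mean(aged$trueCoverageFrac) / mean(young$trueCoverageFrac),
               0.8, tolerance = 0.15)
  expect_equal(mean(aged$trueHrfAmplitude) / mean(young$trueHrfAmplitude),
               0.6, tolerance = 0.15)
  expect_gt(mean(aged$trueHrfLatency), mean(young$trueHrfLatency))
  expect_gt(mean(young$trueArterioleFrac), mean(aged$trueArterioleFrac))
})
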