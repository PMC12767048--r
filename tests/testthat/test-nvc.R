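# NVC epoch analysis: segmentation, normalization, response metrics.

test_that("trial segmentation yields the scheduled windows", {
  tr <- simulateNvcTrace(hrfParams(20, 5, 3, 0), stimSchedule())
  trials <- segmentTrials(tr)
  expect_length(trials, 7)
  for (t in trials) {
    expect_length(t$samples, 450)
    expect_length(t$baselineIdx, 150)
    expect_length(t$stimIdx, 150)
    expect_length(t$postIdx, 150)
  }
  # no overlap, full tiling
  expect_identical(unlist(lapply(trials, function(t)
    t$samples)), tr@samples[1:(7 * 450)])
  short <- new("NvcTrace", samples = tr@samples, schedule = stimSchedule(),
               animalId = "x", group = "")
  short@samples <- short@samples[1:900]
  expect_error(segmentTrials(short), "too short")
  # programmed onsets recovered: response is zero before each onset
  noiseless <- simulateNvcTrace(hrfParams(20, 5, 3, 0), stimSchedule())
  for (t in segmentTrials(noiseless))
    expect_true(all(t$samples[t$baselineIdx] == 100))
})

test_that("baseline normalization is exact and scale-invariant", {
  tr <- simulateNvcTrace(hrfParams(0, 5, 3, 0), stimSchedule())
  t1 <- baselineNormalize(segmentTrials(tr)[[1]])
  expect_true(all(t1$dCbvPct == 0))
  expect_equal(t1$baselineMean, 100)
  # boxcar plateau: baseline 100, stim 120 -> 20%
  box <- segmentTrials(tr)[[1]]
  box$samples[box$stimIdx] <- 120
  bn <- baselineNormalize(box)
  expect_true(all(bn$dCbvPct[bn$stimIdx] == 20))
  # scale invariance
  sc <- box; sc$samples <- box$samples * 3.7
  expect_equal(baselineNormalize(sc)$dCbvPct, bn$dCbvPct)
  bad <- box; bad$samples <- bad$samples * 0
  expect_error(baselineNormalize(bad), "baseline")
})

test_that("trial metrics measure the stimulation window", {
  tr <- simulateNvcTrace(hrfParams(0, 5, 3, 0), stimSchedule())
  box <- segmentTrials(tr)[[1]]
  box$samples[box$stimIdx] <- 120
  m <- trialMetrics(baselineNormalize(box))
  expect_equal(m$averageResponsePct, 20)
  expect_equal(m$peakPct, 20)
  expect_equal(m$timeToPeakS, 0.2) # first stim sample
  flat <- trialMetrics(baselineNormalize(segmentTrials(tr)[[2]]))
  expect_equal(flat$peakPct, 0)
  expect_true(is.na(flat$timeToPeakS))
  # noiseless gamma-variate: peak at the programmed latency
  g <- simulateNvcTrace(hrfParams(20, 5, 3, 0), stimSchedule())
  mg <- trialMetrics(baselineNormalize(segmentTrials(g)[[1]]))
  expect_equal(mg$peakPct, 20, tolerance = 0.5 / 20)
  expect_equal(mg$timeToPeakS, 5, tolerance = 0.2 / 5 + 1e-9)
  expect_gte(mg$peakPct, mg$averageResponsePct)
})

test_that("aggregation reproduces group ordering and SEM identities", {
  sch <- stimSchedule()
  trY <- simulateNvcTrace(hrfParams(20, 5, 3, 0), sch, animalId = "y1",
                          group = "young")
  trA <- simulateNvcTrace(hrfParams(10, 7.5, 3, 0), sch, animalId = "a1",
                          group = "aged")
  tab <- nvcMetricsTable(list(trY, trA))
  expect_equal(nrow(tab), 14)
  agg <- aggregateResponses(tab)
  s <- agg$summary
  peakY <- s$mean[s$group == "young" & s$metric == "peakPct"]
  peakA <- s$mean[s$group == "aged" & s$metric == "peakPct"]
  expect_gt(peakY, peakA)
  ttpY <- s$mean[s$group == "young" & s$metric == "timeToPeakS"]
  ttpA <- s$mean[s$group == "aged" & s$metric == "timeToPeakS"]
  expect_gt(ttpA, ttpY)
  # SEM = SD/sqrt(n) at every time point of the mean curve
  curves <- vapply(lapply(segmentTrials(trY), baselineNormalize),
                   `[[`, numeric(450), "dCbvPct")
  tabY <- tab[tab$group == "young", ]
  aggC <- aggregateResponses(tabY, curves = curves, dtS = 0.2)
  mc <- aggC$meanCurves
  expect_equal(mc$mean, rowMeans(curves))
  expect_equal(mc$sem, apply(curves, 1, sd) / sqrt(7))
  # identical trials -> mean curve equals any single trial
  expect_equal(mc$mean, curves[, 1], tolerance = 1e-12)
})
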