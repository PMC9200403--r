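test_that("reading converts seconds to milliseconds and joins metadata", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("unit_id time_s", "u1 0.010", "u1 0.020", "u2 0.5"), f)
  m <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("unit_id area cell_type ap_mm", "u1 MCC RS 6.5",
               "u2 LPFC weird 3.0"), m)
  expect_warning(trains <- readSpikeTrains(f, m), "unknown cell_type")
  expect_length(trains, 2)
  expect_equal(spikeTimes(trains[["u1"]]), c(10, 20))
  expect_equal(trains[["u1"]]@area, "MCC")
  expect_equal(trains[["u1"]]@cellType, "RS")
  expect_equal(trains[["u2"]]@cellType, "unknown")
})

test_that("empty and malformed spike files are handled", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("unit_id time_s", f)
  expect_identical(readSpikeTrains(f), list())
  writeLines(c("unit_id time_s", "u1 0.020", "u1 0.010"), f)
  expect_error(readSpikeTrains(f), "u1")
})

test_that("write/read round trip preserves times to under a microsecond", {
  tr <- genOuPoisson(5, 300, 3, 10000, seed = 4)$train
  f <- withr::local_tempfile(fileext = ".txt")
  writeSpikeTrains(list(tr), f)
  back <- readSpikeTrains(f)[[1]]
  expect_lt(max(abs(spikeTimes(back) - spikeTimes(tr))), 1e-3)
})

test_that("binning places spikes in half-open bins and conserves counts", {
  tr <- SpikeTrain(1.2, tStart = 0, tStop = 10)
  r <- binRaster(list(tr), binWidth = 0.5, window = c(0, 10))
  expect_equal(as.numeric(rasterCounts(r)[1, ]),
               c(0, 0, 1, rep(0, 17)))
  # edge tie goes to the later bin
  r2 <- binRaster(list(SpikeTrain(0.5, 0, 10)), 0.5, c(0, 10))
  expect_equal(which(rasterCounts(r2)[1, ] == 1), 2)
  # conservation for arbitrary widths
  tr3 <- poissonTrain(10, 1e5, seed = 2)
  for (bw in c(0.5, 3.7, 50)) {
    r3 <- binRaster(list(tr3), bw, c(0, 1e5))
    expect_equal(sum(rasterCounts(r3)), length(spikeTimes(tr3)))
  }
})

test_that("pseudo-population pooling aligns sessions on a common clock", {
  trains <- lapply(1:3, function(s) {
    tr <- poissonTrain(5, 70000, seed = s)
    SpikeTrain(spikeTimes(tr) + s * 1e4, tStart = s * 1e4,
               tStop = s * 1e4 + 70000, unitId = paste0("s", s))
  })
  pp <- buildPseudoPopulation(trains, duration = 60000)
  expect_equal(nrow(rasterCounts(pp)), 3)
  expect_equal(ncol(rasterCounts(pp)), 120000)
  # a short train is excluded with a warning
  short <- SpikeTrain(c(1, 2), 0, 1000, unitId = "short")
  expect_warning(pp2 <- buildPseudoPopulation(c(trains, short), 60000),
                 "excluded")
  expect_equal(nrow(rasterCounts(pp2)), 3)
  # shuffling preserves the total spike count
  sh <- shuffleRaster(pp, seed = 1)
  expect_equal(sum(rasterCounts(sh)), sum(pmin(rasterCounts(pp), 1)))
})

test_that("engage/pause segmentation applies the 60-s rule", {
  mk <- function(starts, len = 4000) {
    TrialEvents(data.frame(trialStart = starts, cueOnset = starts + 500,
                           feedbackOnset = starts + 2500,
                           trialEnd = starts + len))
  }
  ev <- mk(c(0, 10000, 80000))
  iv <- segmentEngagePause(ev)
  tab <- intervalTable(iv)
  expect_equal(tab$label, c("engage", "pause", "engage"))
  expect_equal(tab$t0[2], 14000)  # pause starts when the 2nd trial ends
  expect_equal(tab$t1[2], 80000)
  expect_equal(firstPauseStart(iv), 14000)
  # all gaps below threshold: no pauses
  iv2 <- segmentEngagePause(mk(c(0, 10000, 20000)))
  expect_false("pause" %in% intervalTable(iv2)$label)
  # single trial
  iv3 <- segmentEngagePause(mk(0))
  expect_equal(intervalTable(iv3)$label, "engage")
})

test_that("planted pauses in generated sessions are recovered exactly", {
  g <- genSessionEvents(nTrials = 80, pauseAfter = c(20, 45, 70),
                        pauseDuration = 9e4, seed = 7)
  iv <- segmentEngagePause(g$events)
  expect_equal(sum(intervalTable(iv)$label == "pause"), 3)
  g0 <- genSessionEvents(nTrials = 40, pauseAfter = integer(0), seed = 8)
  expect_false("pause" %in% intervalTable(segmentEngagePause(g0$events))$label)
})

test_that("session generator advances the gauge with correct trials", {
  g <- genSessionEvents(nTrials = 60, rewardProb = 1,
                        blockLengths = 14, seed = 1)
  tab <- trialTable(g$events)
  expect_equal(tab$gaugeStep[14], 7)  # full gauge after 14 rewarded trials
  expect_equal(tab$gaugeStep[15], 1)  # reset at new block
  expect_true(all(tab$blockSpeed == "fast"))
})

test_that("restriction drops spikes outside intervals and keeps structure", {
  tr <- SpikeTrain(c(1000, 5000, 9000), 0, 10000)
  iv <- IntervalSet(0, 4000, "custom")
  expect_equal(spikeTimes(restrictTrain(tr, iv)), 1000)
  # full-range restriction is the identity on spike times
  full <- IntervalSet(0, 10000, "custom")
  expect_equal(spikeTimes(restrictTrain(tr, full)), spikeTimes(tr))
  # interval structure is carried for downstream lag computation
  iv2 <- IntervalSet(c(0, 6000), c(4000, 10000))
  rt <- restrictTrain(tr, iv2)
  expect_equal(nrow(trainIntervals(rt)), 2)
})

test_that("restricted Poisson autocorrelogram shows no gap artifacts", {
  tr <- poissonTrain(8, 3e5, seed = 11)
  # carve the session into kept segments separated by gaps
  keep0 <- seq(0, 3e5 - 3e4, by = 6e4)
  iv <- IntervalSet(keep0, keep0 + 3e4)
  rt <- restrictTrain(tr, iv)
  acR <- spikeAutocorrelogram(rt, minSpikes = 500)
  acU <- spikeAutocorrelogram(tr, minSpikes = 500)
  # both flat: restricted curve should not deviate from the unrestricted
  # one beyond noise (gap-spanning pairs would pile mass at ~30-60 s lags,
  # none of which are below 1 s, but edge effects would tilt the density)
  expect_lt(mean(abs(acR@smoothed - acU@smoothed)), 0.3)
  expect_lt(diff(range(acR@smoothed)), 0.6)
})
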