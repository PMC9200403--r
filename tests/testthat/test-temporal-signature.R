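test_that("spike-count autocorrelation matches analytic cases", {
  # identical counts across bins: perfect correlation at every lag
  counts <- matrix(rep(1:10, 14), nrow = 10)
  ac <- spikeCountAutocorrelation(counts)
  expect_equal(ac@lags, 50 * 1:13)
  expect_true(all(abs(ac@r - 1) < 1e-12))
  # independent counts: correlations near zero
  set.seed(5)
  nTrials <- 400
  ac2 <- spikeCountAutocorrelation(matrix(rpois(nTrials * 14, 5), nTrials))
  expect_true(all(abs(ac2@r) < 3 / sqrt(nTrials)))
  # zero-variance bin is skipped with a warning
  cz <- matrix(rpois(40 * 14, 5), 40); cz[, 3] <- 2
  expect_warning(spikeCountAutocorrelation(cz), "zero-variance")
})

test_that("scTAU fit recovers planted cross-bin correlation timescales", {
  # noiseless exponential curve at the 13 lags
  lags <- 50 * 1:13
  acObj <- new("ScAutocorr", lags = lags,
               r = 0.5 * exp(-lags / 300) + 0.1, nTrials = 100)
  fit <- fitScTau(acObj, seed = 1)
  expect_true(isValid(fit))
  expect_equal(tauValue(fit), 300, tolerance = 1e-4)
  # constant correlation is degenerate
  flat <- new("ScAutocorr", lags = lags, r = rep(0.3, 13), nTrials = 100)
  expect_false(isValid(fitScTau(flat, seed = 1)))
  # counts with exponential cross-bin correlation tau = 200 ms
  set.seed(9)
  S <- exp(-abs(outer(1:14, 1:14, "-")) * 50 / 200)
  x <- MASS::mvrnorm(600, rep(0, 14), S)
  fit2 <- fitScTau(spikeCountAutocorrelation(x), seed = 2)
  expect_true(isValid(fit2))
  expect_equal(tauValue(fit2), 200, tolerance = 0.25)
})

test_that("pooled population scTAU fit stacks units", {
  lags <- 50 * 1:13
  acs <- lapply(1:5, function(i)
    new("ScAutocorr", lags = lags,
        r = 0.5 * exp(-lags / 250) + 0.1 + (i - 3) * 0.01, nTrials = 50))
  fit <- fitScTau(acs, seed = 3)
  expect_true(isValid(fit))
  expect_equal(tauValue(fit), 250, tolerance = 0.05)
})

test_that("exponential segment fits are seeded and validity-checked", {
  ac <- syntheticAC(function(t) 0.6 * exp(-t / 250) + 0.2)
  f1 <- fitExponentialSegment(ac, 1, seed = 7)
  expect_true(isValid(f1))
  expect_equal(tauValue(f1), 250, tolerance = 1e-3)
  expect_equal(f1@A, 0.6, tolerance = 1e-3)
  expect_equal(f1@B, 0.2, tolerance = 1e-3)
  # identical seed gives identical fit; different seed agrees to solver tol
  f2 <- fitExponentialSegment(ac, 1, seed = 7)
  expect_identical(tauValue(f1), tauValue(f2))
  f3 <- fitExponentialSegment(ac, 1, seed = 8)
  expect_equal(tauValue(f3), tauValue(f1), tolerance = 1e-4)
  # fits with a negative offset are invalid
  acNeg <- syntheticAC(function(t) 0.6 * exp(-t / 250) - 0.3)
  expect_false(isValid(fitExponentialSegment(acNeg, 1, seed = 1)))
  # too-short segments never fit
  expect_false(isValid(fitExponentialSegment(ac, 1, 3, seed = 1)))
})

test_that("autocorrelogram has comb structure for periodic trains", {
  ac <- spikeAutocorrelogram(periodicTrain(100, 3e5), minSpikes = 500)
  nonzero <- ac@binCenters[ac@density > 0]
  # all mass at (un-smoothed) multiples of the 100 ms period
  expect_true(all(abs(nonzero %% 100 - 100) < 4 | nonzero %% 100 < 4))
})

test_that("autocorrelogram of a homogeneous Poisson train is flat", {
  ac <- spikeAutocorrelogram(poissonTrain(8, 6e5, seed = 3))
  expect_lt(diff(range(ac@smoothed)), 0.45)
  expect_gt(min(ac@smoothed), 0.4)
})

test_that("too few spikes exclude the unit with a clear reason", {
  tr <- poissonTrain(0.5, 60000, seed = 1)
  expect_error(spikeAutocorrelogram(tr), "excluded")
  sig <- extractSignature(tr)
  expect_false(isValid(sig))
  expect_match(sig@reason, "fewer than")
})

test_that("peak, dip and second peak detection follows the stated rules", {
  # unimodal bump at ~48 ms
  ac <- syntheticAC(function(t) exp(-(t - 48.3)^2 / 500) + 0.2)
  pk <- findAcPeaks(ac)
  expect_equal(pk$lat, 48.3, tolerance = 2)
  expect_null(pk$dip)
  expect_false(pk$degenerate)
  # strictly decreasing: peak forced to first bin, flagged
  ac2 <- syntheticAC(function(t) exp(-t / 300))
  pk2 <- findAcPeaks(ac2)
  expect_equal(pk2$peakIndex, 1)
  expect_true(pk2$degenerate)
  # bump at 30 ms, deep trough at 60 ms, larger bump at 120 ms
  ac3 <- syntheticAC(function(t)
    1.2 * exp(-(t - 30)^2 / 200) + exp(-(t - 120)^2 / 800) +
      0.5 * exp(-t / 400))
  pk3 <- findAcPeaks(ac3)
  expect_false(is.null(pk3$dip))
  expect_false(is.null(pk3$secondPeak))
  expect_gt(ac3@binCenters[pk3$secondPeak], 100)
  # with a strict threshold the shallow trough no longer counts as a dip
  expect_null(findAcPeaks(ac3, dipFraction = 0.01)$dip)
})

test_that("signature recovery is within 20% for OU-rate Poisson trains", {
  taus <- sapply(1:6, function(s) {
    g <- genOuPoisson(5, 300, 3, 6e5, seed = 40 + s)
    tauValue(extractSignature(g$train, seed = s, nRestarts = 25))
  })
  expect_lt(abs(median(taus, na.rm = TRUE) - 300) / 300, 0.2)
})

test_that("TAU is invariant to translation and random thinning", {
  g <- genOuPoisson(8, 300, 5, 6e5, seed = 77)
  tau0 <- tauValue(extractSignature(g$train, seed = 1, nRestarts = 25))
  shifted <- SpikeTrain(spikeTimes(g$train) + 5000, tStart = 5000,
                        tStop = 6e5 + 5000)
  tauS <- tauValue(extractSignature(shifted, seed = 1, nRestarts = 25))
  expect_identical(tauS, tau0)  # translation leaves all lags unchanged
  set.seed(3)
  keep <- runif(length(spikeTimes(g$train))) < 0.6
  thin <- SpikeTrain(spikeTimes(g$train)[keep], tStart = 0, tStop = 6e5)
  tauT <- tauValue(extractSignature(thin, seed = 1, nRestarts = 25))
  expect_lt(abs(tauT - tau0) / tau0, 0.5)
})

test_that("TAU is not correlated with firing rate across units", {
  set.seed(12)
  rates <- runif(40, 2, 20)
  taus <- sapply(seq_along(rates), function(i) {
    g <- genOuPoisson(rates[i], 300, 0.6 * rates[i], 3e5, seed = 500 + i)
    tauValue(extractSignature(g$train, seed = i, nRestarts = 15))
  })
  ok <- !is.na(taus)
  rho <- suppressWarnings(
    cor(rates[ok], taus[ok], method = "spearman"))
  expect_lt(abs(rho), 0.35)
})

test_that("scTAU and TAU agree in rank across a timescale battery", {
  gt <- seq(100, 800, length.out = 8)
  res <- t(sapply(seq_along(gt), function(i) {
    g <- genOuPoisson(8, gt[i], 5, 3e5, seed = 900 + i)
    tau <- tauValue(extractSignature(g$train, seed = i, nRestarts = 15))
    # spike counts in 14 x 50 ms windows tiled over the record
    r <- binRaster(list(g$train), 50, c(0, 3e5))
    cnt <- matrix(rasterCounts(r)[1, 1:(14 * 428)], ncol = 14, byrow = TRUE)
    sc <- tauValue(fitScTau(spikeCountAutocorrelation(cnt), seed = i))
    c(tau = tau, sc = sc)
  }))
  ok <- stats::complete.cases(res)
  expect_gt(cor(res[ok, 1], res[ok, 2], method = "spearman"), 0.35)
})

test_that("fit success rate is high on well-sampled synthetic trains", {
  valid <- sapply(1:12, function(s) {
    g <- genOuPoisson(6, 250, 3.5, 3e5, seed = 200 + s)
    isValid(extractSignature(g$train, seed = s, nRestarts = 25))
  })
  expect_gte(mean(valid), 0.9)
})

test_that("first-order latency matches analytic ISI modes", {
  expect_equal(firstOrderLatency(periodicTrain(100, 2e5)), 100,
               tolerance = 0.04)
  # exponential ISIs: mode at zero, so the first analyzed bin
  expect_lt(firstOrderLatency(poissonTrain(10, 2e5, seed = 2)), 30)
  # gamma(shape 4, mean 100): mode at (4-1) * 25 = 75 ms
  g <- genRenewalBurst(4, 100, duration = 6e5, seed = 5)
  expect_equal(firstOrderLatency(g$train), 75, tolerance = 0.12)
  expect_error(firstOrderLatency(SpikeTrain(c(1, 2, 3), 0, 10)), "ISI")
})

test_that("renewal trains with refractory ISIs give LAT near the ISI mode", {
  g <- genRenewalBurst(8, 120, duration = 6e5, seed = 2)
  sig <- extractSignature(g$train, seed = 1, nRestarts = 25)
  expect_equal(latValue(sig), g$groundTruth$isiMode, tolerance = 0.15)
  expect_null(sig@dip)
})

test_that("burst insertion adds short-lag mass and shifts LAT", {
  g0 <- genRenewalBurst(8, 120, burstProb = 0, duration = 6e5, seed = 3)
  g1 <- genRenewalBurst(8, 120, burstProb = 0.4, intraburstIsi = 5,
                        duration = 6e5, seed = 3)
  ac0 <- spikeAutocorrelogram(g0$train)
  ac1 <- spikeAutocorrelogram(g1$train)
  short <- ac0@binCenters < 40
  expect_gt(mean(ac1@density[short]), mean(ac0@density[short]) + 0.05)
  l0 <- latValue(extractSignature(g0$train, seed = 1, nRestarts = 25))
  l1 <- latValue(extractSignature(g1$train, seed = 1, nRestarts = 25))
  expect_false(isTRUE(all.equal(l0, l1)))
})

test_that("GLOBAL vs FAST+SLOW selection is exercised by dipped curves", {
  # construct a train whose AC has a burst bump, a trough, then slow decay
  g <- genRenewalBurst(8, 180, burstProb = 0.9, intraburstIsi = 8,
                       burstLength = 2, duration = 6e5, seed = 21)
  ac <- spikeAutocorrelogram(g$train)
  pk <- findAcPeaks(ac)
  sig <- extractSignature(g$train, seed = 1, nRestarts = 25)
  # whatever the dip outcome, the returned fit must be a GLOBAL fit and the
  # selection rule must have produced a definite answer
  if (isValid(sig)) expect_equal(sig@fit@kind, "GLOBAL")
  else expect_match(sig@reason, "GLOBAL")
})

test_that("signature tables carry the full per-unit record", {
  g <- genOuPoisson(6, 200, 3, 2e5, seed = 31)
  sig <- extractSignature(g$train, seed = 1, nRestarts = 15)
  tab <- signatureTable(list(sig), list(g$train))
  expect_named(tab, c("unit_id", "area", "cell_type", "LAT_ms", "TAU_ms",
                      "A", "B", "rmse", "valid", "scTAU_ms", "n_spikes"))
  expect_equal(tab$TAU_ms, tauValue(sig))
})
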