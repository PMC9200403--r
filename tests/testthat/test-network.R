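test_that("synaptic matrices have the prescribed block structure", {
  p <- networkParams("LPFCm")
  syn <- buildNetwork(p, seed = 1)
  W <- synapticWeights(syn)
  expect_true(all(diag(W) == 0))
  expect_true(all(W >= 0))
  eIdx <- which(isExcitatory(syn)); iIdx <- which(!isExcitatory(syn))
  # realized densities within ~3 binomial s.e. of the targets
  dEE <- mean(W[eIdx, eIdx][upper.tri(W[eIdx, eIdx]) |
                              lower.tri(W[eIdx, eIdx])] > 0)
  expect_equal(dEE, 0.3, tolerance = 0.03)
  expect_equal(mean(W[eIdx, iIdx] > 0), 0.3, tolerance = 0.05)
  expect_equal(mean(W[iIdx, eIdx] > 0), 0.55, tolerance = 0.05)
  # log-normal weights: moment-matched mean and sd
  w <- W[W > 0]
  expect_equal(mean(w), 0.03, tolerance = 0.02)
  expect_equal(sd(w), 0.02, tolerance = 0.1)
})

test_that("reciprocal E-E motifs are over-represented by the set factor", {
  # at pEE = 0.2 the 4x factor is feasible: P(bidir) = 4 * 0.04 = 0.16
  p <- networkParams("LPFCm", pEE = 0.2)
  nBi <- 0; nPair <- 0; marg <- 0; nM <- 0
  for (s in 1:4) {
    syn <- buildNetwork(p, seed = s)
    W <- synapticWeights(syn)
    e <- which(isExcitatory(syn))
    A <- W[e, e] > 0
    up <- upper.tri(A)
    nBi <- nBi + sum(A[up] & t(A)[up])
    nPair <- nPair + sum(up)
    marg <- marg + sum(A[up]) + sum(t(A)[up]); nM <- nM + 2 * sum(up)
  }
  expect_equal(nBi / nPair, 4 * 0.2^2, tolerance = 0.05)
  expect_equal(marg / nM, 0.2, tolerance = 0.03)   # marginal preserved
  # at pEE = 0.3 the factor saturates at 1/p (all E-E pairs reciprocal)
  syn3 <- buildNetwork(networkParams("LPFCm"), seed = 2)
  W3 <- synapticWeights(syn3)
  e <- which(isExcitatory(syn3)); A3 <- W3[e, e] > 0
  up <- upper.tri(A3)
  expect_equal(sum(A3[up] & t(A3)[up]) / sum(up), 0.3, tolerance = 0.02)
  expect_lt(sum(xor(A3[up], t(A3)[up])) / sum(up), 0.005)
})

test_that("per-neuron inhibitory conductances satisfy recurrent balance", {
  p <- networkParams("MCCm")
  syn <- buildNetwork(p, seed = 3)
  W <- synapticWeights(syn)
  eIdx <- which(isExcitatory(syn)); iIdx <- which(!isExcitatory(syn))
  sumE <- colSums(W[eIdx, ]); sumI <- colSums(W[iIdx, ])
  Vm <- p$Vmean
  lhs <- syn@gGABAA * (Vm - p$VGABAA) * sumI
  rhs <- -p$gGABAA * (Vm - p$VAMPA) * sumE
  expect_equal(lhs, rhs, tolerance = 1e-10)
  lhsB <- syn@gGABAB * (Vm - p$VGABAB) * sumI
  rhsB <- -p$gGABAB * (Vm - p$VAMPA) * sumE
  expect_equal(lhsB, rhsB, tolerance = 1e-10)
})

test_that("a silent network stays silent and relaxes to rest", {
  # CAN/AHP at basal calcium shift the resting point; turn them off to test
  # the bare leak fixed point
  p <- smallNetParams(pAMPAFF = 0, gCAN = 0, gAHP = 0)
  syn <- buildNetwork(p, seed = 1)
  syn@weights[] <- 0
  sim <- simulateNetwork(p, syn, duration = 1000, seed = 1)
  expect_equal(nrow(spikeRaster(sim)), 0)
  Vend <- sim@snapshots[["final"]]$V
  expect_true(all(abs(Vend - p$Vrest) < 0.5))
})

test_that("LPFCm preset produces asynchronous irregular activity", {
  p <- networkParams("LPFCm")
  syn <- buildNetwork(p, seed = 4)
  sim <- simulateNetwork(p, syn, duration = 20000, seed = 4)
  st <- spikingStatistics(sim, minSpikes = 50)
  expect_gt(nrow(st), 100)
  expect_lt(mean(st$rate_hz), 20)
  cv <- mean(st$cv)
  expect_gt(cv, 0.5); expect_lt(cv, 1.5)
  # no spikes violate the 3-ms refractory period
  sp <- spikeRaster(sim)
  minIsi <- min(unlist(tapply(sp$time, sp$neuron,
                              function(x) if (length(x) > 1) min(diff(x))
                              else Inf)))
  expect_gte(minIsi, p$refractory)
})

test_that("snapshots restore the trajectory bit-identically", {
  p <- smallNetParams()
  syn <- buildNetwork(p, seed = 5)
  full <- simulateNetwork(p, syn, duration = 4000, seed = 5,
                          snapshotTimes = 2000)
  resumed <- simulateNetwork(p, syn, duration = 2000,
                             init = full@snapshots[["2000"]])
  spFull <- spikeRaster(full)
  tail <- spFull[spFull$time > 2000, ]
  expect_equal(resumed@spikes$neuron, tail$neuron)
  expect_equal(resumed@spikes$time + 2000, tail$time)
})

test_that("gating, openings and calcium respect physical bounds", {
  p <- networkParams("MCCm")
  syn <- buildNetwork(p, seed = 6)
  sim <- simulateNetwork(p, syn, duration = 5000, seed = 6)
  st <- sim@snapshots[["final"]]
  for (f in c("pCAN", "pAHP", "pA", "qN", "pN", "pGA", "qB", "pB")) {
    expect_gte(min(st[[f]]), 0)
    expect_lte(max(st[[f]]), 1)
  }
  expect_gte(min(st$Ca), 0)
  expect_true(all(st$V <= p$theta + 1e-9))
})

test_that("AHP acts only on excitatory neurons", {
  # in a decoupled network inhibitory dynamics are identical across gAHP
  p1 <- smallNetParams(gAHP = 0.02)
  p2 <- smallNetParams(gAHP = 0.3)
  syn <- buildNetwork(p1, seed = 7)
  syn@weights[] <- 0
  s1 <- simulateNetwork(p1, syn, duration = 5000, seed = 7)
  s2 <- simulateNetwork(p2, syn, duration = 5000, seed = 7)
  inh <- which(!isExcitatory(syn))
  sp1 <- spikeRaster(s1); sp2 <- spikeRaster(s2)
  i1 <- sp1[sp1$neuron %in% inh, ]; rownames(i1) <- NULL
  i2 <- sp2[sp2$neuron %in% inh, ]; rownames(i2) <- NULL
  expect_identical(i1, i2)
  # and excitatory firing decreases with gAHP under the same drive
  exc <- which(isExcitatory(syn))
  expect_lt(sum(sp2$neuron %in% exc), sum(sp1$neuron %in% exc))
})

test_that("spiking statistics match analytic expectations", {
  # periodic train: CV = CV2 = Lv = 0
  per <- simFromSpikes(seq(10, 99990, by = 10), duration = 1e5)
  st <- spikingStatistics(per, minSpikes = 50)
  expect_equal(st$cv, 0, tolerance = 1e-10)
  expect_equal(st$lv, 0, tolerance = 1e-10)
  # Poisson train: CV and Fano near 1 (5% at 1e4 spikes)
  tr <- poissonTrain(100, 1e5, seed = 9)
  ps <- simFromSpikes(spikeTimes(tr), duration = 1e5)
  stp <- spikingStatistics(ps, minSpikes = 50)
  expect_equal(stp$cv, 1, tolerance = 0.05)
  expect_equal(stp$fano, 1, tolerance = 0.1)
})

test_that("a one-point network sweep is deterministic", {
  g <- data.frame(gAHP = 0.022, gGABAB = 0.0035)
  p <- smallNetParams()
  t1 <- sweepNetwork(g, p, reps = 1, duration = 20000, seed = 11,
                     minSpikes = 60)
  t2 <- sweepNetwork(g, p, reps = 1, duration = 20000, seed = 11,
                     minSpikes = 60)
  expect_identical(t1, t2)
  expect_named(t1, c("gAHP", "gGABAB", "LAT_exc", "TAU_exc", "LAT_inh",
                     "TAU_inh", "rate_hz", "fracValid", "flagged"))
})
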