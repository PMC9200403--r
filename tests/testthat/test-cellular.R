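test_that("background steady states follow the kinetic formulas", {
  bg <- configureBackground(ouBackgroundParams())
  # first-order: m = (1 + (tau dp f n)^-1)^-1 with the printed constants
  expect_equal(bg$mAMPA,
               1 / (1 + 1 / (2.5 * 0.1 * (7 / 1000) * 484)),
               tolerance = 1e-12)
  expect_equal(bg$mGABAA,
               1 / (1 + 1 / (10 * 0.1 * (7 / 1000) * 121)),
               tolerance = 1e-12)
  # second-order analogue for NMDA
  qs <- 1 / (1 + 1 / (4.65 * 0.1 * (7 / 1000) * 484))
  expect_equal(bg$mNMDA, 1 / (1 + 1 / (0.275 * 75 * qs)), tolerance = 1e-12)
  expect_equal(bg$sigmaAMPA, bg$mAMPA / 2)
  # saturation: infinite presynaptic rate drives m to 1
  bgInf <- configureBackground(ouBackgroundParams(fExc = 1e9, fInh = 1e9))
  expect_equal(bgInf$mAMPA, 1, tolerance = 1e-6)
  expect_equal(bgInf$mNMDA, 1 / (1 + 1 / (0.275 * 75)), tolerance = 1e-4)
  # degenerate input
  expect_error(configureBackground(ouBackgroundParams(fExc = 0)),
               "degenerate")
})

test_that("inhibitory conductances satisfy the balance identity", {
  bg <- configureBackground(ouBackgroundParams())
  Vm <- bg$Vmean
  # driving-force x count-ratio balance, receptor by receptor
  expect_equal(bg$gGABAAbar * (Vm - bg$VGABAA) * bg$nInh,
               -bg$gGABAA * (Vm - bg$VAMPA) * bg$nExc, tolerance = 1e-10)
  expect_equal(bg$gGABABbar * (Vm - bg$VGABAB) * bg$nInh,
               -bg$gGABAB * (Vm - bg$VAMPA) * bg$nExc, tolerance = 1e-10)
})

test_that("NMDA magnesium block matches the closed form", {
  expect_equal(nmdaMgBlock(0, 1.5), 1 / (1 + 1.5 / 3.57), tolerance = 1e-12)
  expect_equal(nmdaMgBlock(0, 1.5), 0.704, tolerance = 1e-3)
  expect_lt(nmdaMgBlock(-70), nmdaMgBlock(0))
})

test_that("leak-only cell rests at the leak reversal with no spikes", {
  p0 <- cellularParams(gNa = 0, gK = 0, gCaL = 0, gCAN = 0, gAHP = 0)
  bg0 <- configureBackground(ouBackgroundParams())
  bg0 <- setParams(bg0, mAMPA = 0, mNMDA = 0, mGABAA = 0, mGABAB = 0,
                   sigmaAMPA = 0, sigmaNMDA = 0, sigmaGABAA = 0,
                   sigmaGABAB = 0)
  cs <- simulateCell(p0, bg0, duration = 2000, seed = 1)
  expect_equal(cs$V_end, -70, tolerance = 1e-6)
  expect_length(spikeTimes(cs$train), 0)
})

test_that("default cell fires irregularly below the 20 Hz realism bound", {
  rates <- sapply(1:3, function(s) {
    cs <- simulateCell(cellularParams(), duration = 20000, seed = s)
    length(spikeTimes(cs$train)) / 20
  })
  expect_lt(mean(rates), 20)
  expect_gt(mean(rates), 0.5)  # not silent either
})

test_that("zero-noise simulation is deterministic and Euler-convergent", {
  bg0 <- configureBackground(ouBackgroundParams())
  bg0 <- setParams(bg0, sigmaAMPA = 0, sigmaNMDA = 0, sigmaGABAA = 0,
                   sigmaGABAB = 0)
  a <- simulateCell(cellularParams(), bg0, duration = 2000, seed = 1,
                    traces = TRUE)
  b <- simulateCell(cellularParams(), bg0, duration = 2000, seed = 99,
                    traces = TRUE)
  expect_identical(a$traces$V, b$traces$V)  # seed-independent when sigma=0
  # halving dt changes the trajectory by < 1 mV RMS
  h <- simulateCell(cellularParams(), bg0, duration = 2000, seed = 1,
                    dt = 0.05, traces = TRUE)
  vh <- h$traces$V[seq(2, nrow(h$traces), by = 2)]
  rms <- sqrt(mean((a$traces$V - vh)^2))
  expect_lt(rms, 1)
})

test_that("calcium and gating stay in their physical ranges", {
  cs <- simulateCell(cellularParams(), duration = 10000, seed = 5,
                     traces = TRUE)
  expect_gte(min(cs$traces$Ca), 0)
  expect_gte(min(cs$traces$pCAN), 0)
  expect_lte(max(cs$traces$pCAN), 1)
  expect_gte(min(cs$traces$pAHP), 0)
  expect_lte(max(cs$traces$pAHP), 1)
})

test_that("AHP strengthens the refractory gap", {
  q <- sapply(c(0, 0.05, 0.15), function(g) {
    cs <- simulateCell(cellularParams(gAHP = g), duration = 30000, seed = 2)
    isi <- diff(spikeTimes(cs$train))
    quantile(isi, 0.1)
  })
  expect_true(all(diff(q) > 0))
})

test_that("cellular sweeps record signatures and apply the rate bound", {
  grid <- data.frame(gAHP = c(0.05, 0.15))
  t1 <- sweepCellular(grid, duration = 60000, seed = 3, minSpikes = 200)
  expect_equal(nrow(t1), 2)
  expect_named(t1, c("gAHP", "rep", "LAT_ms", "TAU_ms", "rate_hz",
                     "discarded", "valid"))
  expect_true(all(t1$discarded == (t1$rate_hz > 20)))
  # rerun with the same seeds is identical
  t2 <- sweepCellular(grid, duration = 60000, seed = 3, minSpikes = 200)
  expect_identical(t1, t2)
  # zero-conductance baseline runs without error
  t0 <- sweepCellular(data.frame(gCAN = 0, gAHP = 0), duration = 20000,
                      seed = 1, minSpikes = 100)
  expect_equal(nrow(t0), 1)
})
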