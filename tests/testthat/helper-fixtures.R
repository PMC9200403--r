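# shared fixture builders; everything is generated in code at test time

# homogeneous Poisson train
poissonTrain <- function(rate = 5, duration = 6e5, seed = 1) {
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed(seed, {
    n <- rpois(1, rate * duration / 1000)
    SpikeTrain(sort(runif(n, 0, duration)), tStart = 0, tStop = duration,
               unitId = sprintf("poisson%d", seed))
  })
}

# perfectly periodic train
periodicTrain <- function(period = 100, duration = 6e5) {
  SpikeTrain(seq(period, duration - 1, by = period), tStart = 0,
             tStop = duration, unitId = "periodic")
}

# synthetic smoothed autocorrelogram object from a function of lag
syntheticAC <- function(f) {
  centers <- (4:300 - 0.5) * 10 / 3
  y <- f(centers)
  new("SpikeAutocorr", binCenters = centers, density = y, smoothed = y,
      nSpikes = 10000)
}

# tiny deterministic SimResult from explicit spike times
simFromSpikes <- function(times, neuron = 1, nNeurons = 1,
                          duration = max(times) + 1, isExc = TRUE) {
  new("SimResult",
      spikes = data.frame(neuron = rep(neuron, length.out = length(times)),
                          time = times),
      nNeurons = nNeurons, isExc = rep(isExc, length.out = nNeurons),
      duration = duration, dt = 0.5, snapshots = list(), seed = 0)
}

# small network params for fast simulation tests
smallNetParams <- function(preset = "LPFCm", N = 100, ...) {
  nE <- round(0.8 * N); nI <- N - nE
  networkParams(preset, N = N, nExc = nE, nInh = nI, ...)
}
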