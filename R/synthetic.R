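#' OU-rate Poisson spike train generator
#'
#' Doubly stochastic Poisson process whose rate follows an
#' Ornstein-Uhlenbeck process with time constant \code{tau}, rectified at
#' zero. The spike autocorrelogram of such a train decays exponentially with
#' time constant approximately \code{tau}, emulating units with a
#' controllable intrinsic timescale. Rectification (rather than reflection)
#' keeps the autocorrelation approximately exponential as long as the
#' rectified fraction is small; a warning is issued beyond 20%.
#'
#' @param meanRate mean firing rate (Hz).
#' @param tau rate-fluctuation time constant (ms), 10-1000.
#' @param rateSd standard deviation of the rate fluctuations (Hz).
#' @param duration train duration (ms).
#' @param seed integer seed.
#' @param dt rate-process resolution (ms).
#' @param returnRate also return the latent (rectified) rate trace.
#' @return list(train = \linkS4class{SpikeTrain}, groundTruth = list(...),
#'   and \code{rate} when requested).
#' @export
genOuPoisson <- function(meanRate = 5, tau = 300, rateSd = 3,
                         duration = 6e5, seed = 1, dt = 1,
                         returnRate = FALSE) {
  stopifnot(meanRate > 0, tau >= 10, tau <= 1000)
  withSeed(seed, {
    n <- ceiling(duration / dt)
    a <- exp(-dt / tau)
    innov <- stats::rnorm(n, 0, rateSd * sqrt(1 - a^2))
    lam <- meanRate + as.numeric(stats::filter(innov, a, "recursive",
                                               init = stats::rnorm(1, 0, rateSd)))
    rectFrac <- mean(lam < 0)
    if (rectFrac > 0.2)
      warning(sprintf("%.0f%% of the OU rate is rectified at zero; \
autocorrelation shape degraded", 100 * rectFrac))
    lam <- pmax(lam, 0)
    counts <- stats::rpois(n, lam * dt / 1000)
    idx <- rep.int(seq_len(n), counts)
    ts <- sort((idx - 1) * dt + stats::runif(length(idx), 0, dt))
    ts <- ts[!duplicated(ts)]
    out <- list(train = SpikeTrain(ts, tStart = 0, tStop = duration,
                                   unitId = sprintf("ou_tau%d_seed%d",
                                                    round(tau),
                                                    as.integer(seed))),
                groundTruth = list(kind = "ou_poisson", meanRate = meanRate,
                                   tau = tau, rateSd = rateSd,
                                   rectifiedFraction = rectFrac,
                                   seed = seed))
    if (returnRate) out$rate <- lam
    out
  })
}

#' Gamma-renewal spike train generator with optional bursts
#'
#' Core inter-spike intervals are gamma distributed with shape
#' \code{isiShape} and mean \code{isiMean} (analytic ISI mode
#' (shape - 1) * scale), so increasing the shape emulates an increasing
#' relative refractory period, which shifts the autocorrelogram peak latency.
#' With probability \code{burstProb} each core spike is followed by a short
#' burst of \code{burstLength} extra spikes at \code{intraburstIsi} spacing,
#' adding autocorrelogram mass at short lags.
#'
#' @param isiShape gamma shape (>= 1).
#' @param isiMean mean core ISI (ms).
#' @param burstProb per-spike burst probability.
#' @param intraburstIsi spacing of burst spikes (ms).
#' @param burstLength extra spikes per burst.
#' @param duration train duration (ms).
#' @param seed integer seed.
#' @return list(train, groundTruth) with the analytic ISI mode in the ground
#'   truth.
#' @export
genRenewalBurst <- function(isiShape = 4, isiMean = 120, burstProb = 0,
                            intraburstIsi = 5, burstLength = 3,
                            duration = 6e5, seed = 1) {
  stopifnot(isiShape >= 1, isiMean > 0)
  withSeed(seed, {
    scale <- isiMean / isiShape
    nExp <- ceiling(duration / isiMean * 1.3) + 50
    isi <- stats::rgamma(nExp, shape = isiShape, scale = scale)
    ts <- cumsum(isi)
    while (ts[length(ts)] < duration) {
      isi2 <- stats::rgamma(nExp, shape = isiShape, scale = scale)
      ts <- c(ts, ts[length(ts)] + cumsum(isi2))
    }
    ts <- ts[ts < duration]
    if (burstProb > 0) {
      doBurst <- stats::runif(length(ts)) < burstProb
      extra <- unlist(lapply(which(doBurst), function(i)
        ts[i] + seq_len(burstLength) * intraburstIsi))
      ts <- sort(c(ts, extra))
      ts <- ts[ts < duration]
      ts <- ts[c(TRUE, diff(ts) > 1e-9)]
    }
    list(train = SpikeTrain(ts, tStart = 0, tStop = duration,
                            unitId = sprintf("renewal_shape%g_seed%d",
                                             isiShape, as.integer(seed))),
         groundTruth = list(kind = "renewal_burst", isiShape = isiShape,
                            isiMean = isiMean,
                            isiMode = (isiShape - 1) * scale,
                            burstProb = burstProb, seed = seed))
  })
}

#' Markov-switching population raster generator
#'
#' A hidden Markov chain with exponential (optionally log-normal) dwell
#' times and uniform transitions between distinct states; each state sets a
#' per-neuron Poisson firing rate. Spikes are binned at \code{binWidth}
#' (sparse storage), and the ground-truth state sequence is returned for
#' HMM-recovery validation.
#'
#' @param nStates number of hidden states.
#' @param nNeurons number of neurons.
#' @param rates K x N matrix of per-state per-neuron rates (Hz), or a
#'   length-K vector recycled over neurons.
#' @param meanDurations length-K mean state dwell times (ms), >= 10 ms.
#' @param duration total raster duration (ms).
#' @param seed integer seed.
#' @param binWidth raster bin (ms).
#' @param lognormalDwell draw dwell times log-normally (same mean, sigma-log
#'   0.5) instead of exponentially.
#' @return list(raster = \linkS4class{PopulationRaster},
#'   states = \linkS4class{StateSequence} ground truth, groundTruth).
#' @export
genMarkovRaster <- function(nStates = 4, nNeurons = 60,
                            rates = c(2, 5, 10, 20),
                            meanDurations = c(100, 300, 1000, 3000),
                            duration = 6e5, seed = 1, binWidth = 0.5,
                            lognormalDwell = FALSE) {
  stopifnot(all(meanDurations >= 10))
  if (is.null(dim(rates)))
    rates <- matrix(rep(rates, nNeurons), nrow = nStates)
  stopifnot(nrow(rates) == nStates, ncol(rates) == nNeurons,
            all(rates >= 0))
  if (nStates > 1 &&
      any(duplicated(split(rates, seq_len(nStates)))))
    warning("some states have identical rate vectors; indistinguishable")
  withSeed(seed, {
    # hidden chain
    st <- integer(0); t0 <- numeric(0); t1 <- numeric(0)
    cur <- sample.int(nStates, 1); t <- 0
    while (t < duration) {
      d <- if (lognormalDwell) {
        sl <- 0.5
        stats::rlnorm(1, log(meanDurations[cur]) - sl^2 / 2, sl)
      } else stats::rexp(1, 1 / meanDurations[cur])
      d <- max(d, binWidth)
      st <- c(st, cur); t0 <- c(t0, t); t1 <- c(t1, min(t + d, duration))
      t <- t + d
      if (nStates > 1) {
        cand <- setdiff(seq_len(nStates), cur)
        cur <- cand[sample.int(length(cand), 1)]
      }
    }
    # spikes per period x neuron
    iAll <- integer(0); jAll <- integer(0)
    nBins <- ceiling(duration / binWidth)
    for (k in seq_along(st)) {
      dur <- t1[k] - t0[k]
      lam <- rates[st[k], ] * dur / 1000
      cnt <- stats::rpois(nNeurons, lam)
      tot <- sum(cnt)
      if (!tot) next
      nn <- rep.int(seq_len(nNeurons), cnt)
      tt <- t0[k] + stats::runif(tot, 0, dur)
      bb <- pmin(floor(tt / binWidth) + 1L, nBins)
      iAll <- c(iAll, nn); jAll <- c(jAll, bb)
    }
    counts <- Matrix::sparseMatrix(i = iAll, j = jAll, x = 1,
                                   dims = c(nNeurons, nBins))
    raster <- new("PopulationRaster", counts = counts, binWidth = binWidth,
                  tStart = 0, neuronMeta = data.frame())
    labels <- st[findInterval(
      (seq_len(nBins) - 0.5) * binWidth, t0)]
    periods <- data.frame(state = st, t0 = t0, t1 = t1,
                          duration = t1 - t0)
    seqTruth <- new("StateSequence", labels = as.integer(labels),
                    binWidth = binWidth, periods = periods,
                    rawPeriods = periods)
    list(raster = raster, states = seqTruth,
         groundTruth = list(kind = "markov_raster", nStates = nStates,
                            rates = rates, meanDurations = meanDurations,
                            seed = seed))
  })
}

#' Session event-log generator
#'
#' Emits a plausible session of self-initiated trials for segmentation
#' tests: trials of fixed internal structure (cue 500 ms after start,
#' feedback 2.5 s, end 4 s), inter-trial gaps of 2 s, pauses of >= 60 s
#' planted after specified trials, rewards drawn at \code{rewardProb}, and a
#' gauge advancing one of seven steps as correct trials accumulate within
#' blocks of 14, 21, 28 or 35 correct trials (block speeds "fast" for 14/21,
#' "slow" for 28/35).
#'
#' @param nTrials number of trials.
#' @param pauseAfter integer trial indices after which a pause is planted.
#' @param pauseDuration pause length (ms), >= 60 s.
#' @param rewardProb probability of a rewarded (correct) trial.
#' @param blockLengths pool of correct-trial counts to fill the gauge.
#' @param seed integer seed.
#' @return list(events = \linkS4class{TrialEvents}, groundTruth).
#' @export
genSessionEvents <- function(nTrials = 100, pauseAfter = integer(0),
                             pauseDuration = 9e4, rewardProb = 0.8,
                             blockLengths = c(14, 21, 28, 35), seed = 1) {
  stopifnot(pauseDuration >= 6e4)
  withSeed(seed, {
    iti <- 2000; trialLen <- 4000
    drawBlock <- function() blockLengths[sample.int(length(blockLengths), 1)]
    blockLen <- drawBlock()
    speed <- if (blockLen <= 21) "fast" else "slow"
    nCorrect <- 0
    t <- 0
    rows <- vector("list", nTrials)
    for (i in seq_len(nTrials)) {
      rewarded <- stats::runif(1) < rewardProb
      gaugeStep <- min(7L, floor(nCorrect / blockLen * 7) + 1L)
      rows[[i]] <- data.frame(
        trialStart = t, cueOnset = t + 500, feedbackOnset = t + 2500,
        trialEnd = t + trialLen,
        choice = "work",
        feedback = if (rewarded) "reward" else "noreward",
        gaugeStep = gaugeStep, blockSpeed = speed)
      if (rewarded) nCorrect <- nCorrect + 1
      if (nCorrect >= blockLen) {  # gauge full: new block
        nCorrect <- 0
        blockLen <- drawBlock()
        speed <- if (blockLen <= 21) "fast" else "slow"
      }
      t <- t + trialLen + iti
      if (i %in% pauseAfter) t <- t + pauseDuration
    }
    ev <- TrialEvents(do.call(rbind, rows))
    list(events = ev,
         groundTruth = list(kind = "session_events", nTrials = nTrials,
                            pauseAfter = pauseAfter,
                            pauseDuration = pauseDuration, seed = seed))
  })
}
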