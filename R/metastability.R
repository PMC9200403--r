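#' HMM configuration
#'
#' @param nStates number of hidden states (default 4, the parsimonious
#'   choice backed by the AIC/BIC scan over 2-10 states).
#' @param binWidth emission bin (ms).
#' @param threshold posterior threshold below which a bin is the null state
#'   S0.
#' @param initMeanDuration initial mean state duration (ms) setting the
#'   self-transition prior p_stay = 1 - bin/initMeanDuration.
#' @param maxPeriod periods longer than this (ms) are excluded from duration
#'   statistics.
#' @param nInits EM restarts (100 were used on monkey-scale data; fewer
#'   suffice for model rasters).
#' @param maxIter,tol EM stopping rule (relative log-likelihood change).
#' @return list of settings.
#' @export
hmmConfig <- function(nStates = 4, binWidth = 0.5, threshold = 0.8,
                      initMeanDuration = 300, maxPeriod = 3e5,
                      nInits = 5, maxIter = 500, tol = 1e-6) {
  stopifnot(threshold > 0.5, threshold <= 1, nStates >= 2)
  list(nStates = nStates, binWidth = binWidth, threshold = threshold,
       initMeanDuration = initMeanDuration, maxPeriod = maxPeriod,
       nInits = nInits, maxIter = maxIter, tol = tol)
}

# binarized CSR representation (spk: 0-based neuron per spike, ptr: length
# T+1 bin offsets) of a raster or simulation
.toCSR <- function(x, binWidth = 0.5, duration = NULL, neurons = NULL) {
  if (is(x, "PopulationRaster")) {
    cnt <- x@counts
    if (is(cnt, "sparseMatrix")) {
      cnt <- methods::as(methods::as(cnt, "CsparseMatrix"), "generalMatrix")
      return(list(spk = cnt@i, ptr = cnt@p, nNeurons = nrow(cnt),
                  T = ncol(cnt), binWidth = x@binWidth))
    }
    spk <- integer(0); ptr <- integer(ncol(cnt) + 1)
    idx <- which(cnt > 0, arr.ind = TRUE)
    ord <- order(idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    ptr <- c(0L, cumsum(tabulate(idx[, 2], nbins = ncol(cnt))))
    return(list(spk = as.integer(idx[, 1] - 1L), ptr = as.integer(ptr),
                nNeurons = nrow(cnt), T = ncol(cnt), binWidth = x@binWidth))
  }
  if (is(x, "SimResult")) {
    if (is.null(duration)) duration <- x@duration
    sp <- x@spikes
    nb <- as.integer(round(duration / binWidth))
    bin <- pmin(as.integer(ceiling(sp$time / binWidth)), nb)
    keep <- bin >= 1
    bin <- bin[keep]; neu <- sp$neuron[keep]
    dup <- duplicated(data.frame(bin, neu))
    bin <- bin[!dup]; neu <- neu[!dup]
    ord <- order(bin)
    ptr <- c(0L, cumsum(tabulate(bin, nbins = nb)))
    return(list(spk = as.integer(neu[ord] - 1L), ptr = as.integer(ptr),
                nNeurons = x@nNeurons, T = nb, binWidth = binWidth))
  }
  stop("unsupported input for HMM fitting")
}

#' Fit a Bernoulli-emission HMM to population spiking
#'
#' EM-trained hidden Markov model over binarized spike rasters at fine time
#' bins (default 0.5 ms), with independent per-neuron Bernoulli emissions
#' per state. The self-transition probability is initialized from the
#' 300-ms mean-duration prior (p_stay = 1 - bin/300); emission
#' probabilities are initialized from per-neuron mean rates perturbed by
#' state-specific log-normal factors, and the best of \code{nInits}
#' restarts (highest log-likelihood) is kept.
#'
#' @param x a \linkS4class{PopulationRaster} or \linkS4class{SimResult}.
#' @param cfg an \code{\link{hmmConfig}}.
#' @param seed integer seed for the restarts (and, for multinomial
#'   emissions, the random selection among simultaneous spikes).
#' @param binWidth bin width used when \code{x} is a SimResult.
#' @param emission emission family: "bernoulli" (independent per-neuron
#'   spike probabilities per bin; the default) or "multinomial" (each bin
#'   encoded by the identity of the spiking neuron with ties broken at
#'   random, or silence). The multinomial encoding carries less evidence
#'   per bin, which lengthens ambiguous (null-state) episodes and makes
#'   decoded states sensitive to the random tie-breaking; it is the
#'   classical population-HMM encoding.
#' @return An \linkS4class{HMMFit} (posteriors of the best restart
#'   included).
#' @export
fitHMM <- function(x, cfg = hmmConfig(), seed = 1, binWidth = cfg$binWidth,
                   emission = c("bernoulli", "multinomial")) {
  emission <- match.arg(emission)
  csr <- .toCSR(x, binWidth = binWidth)
  K <- cfg$nStates
  N <- csr$nNeurons
  pstay <- 1 - csr$binWidth / cfg$initMeanDuration
  transInit <- matrix((1 - pstay) / (K - 1), K, K)
  diag(transInit) <- pstay
  best <- NULL
  if (emission == "bernoulli") {
    baseRate <- tabulate(csr$spk + 1L, nbins = N) / csr$T
    baseRate <- pmin(pmax(baseRate, 1e-6), 1 - 1e-6)
    withSeed(seed, {
      for (r in seq_len(cfg$nInits)) {
        emisInit <- matrix(NA_real_, K, N)
        for (k in seq_len(K))
          emisInit[k, ] <- pmin(pmax(
            baseRate * stats::rlnorm(N, 0, 0.7), 1e-6), 1 - 1e-6)
        fit <- .hmm_em(csr$spk, csr$ptr, N, transInit, emisInit,
                       rep(1 / K, K), cfg$maxIter, cfg$tol, TRUE)
        if (is.null(best) || fit$logLik > best$logLik) best <- fit
      }
    })
  } else {
    withSeed(seed, {
      sym <- .csrSymbols(csr)
      freq <- tabulate(sym + 1L, nbins = N + 1) / length(sym)
      freq <- pmax(freq, 1e-8)
      for (r in seq_len(cfg$nInits)) {
        emisInit <- matrix(NA_real_, K, N + 1)
        for (k in seq_len(K)) {
          row <- freq * stats::rlnorm(N + 1, 0, 0.7)
          emisInit[k, ] <- row / sum(row)
        }
        fit <- .hmm_em_multi(sym, N + 1L, transInit, emisInit,
                             rep(1 / K, K), cfg$maxIter, cfg$tol, TRUE)
        if (is.null(best) || fit$logLik > best$logLik) best <- fit
      }
    })
  }
  if (!best$converged)
    warning("EM stopped at the iteration cap; best iterate returned")
  new("HMMFit", transition = best$transition, emission = best$emission,
      initProb = as.numeric(best$initProb), logLik = best$logLik,
      posteriors = best$posteriors, binWidth = csr$binWidth,
      emissionType = emission, converged = best$converged)
}

# one symbol per bin from a CSR raster: the spiking neuron's 1-based index,
# a uniformly random choice among simultaneous spikes, 0 for silence; uses
# the current RNG stream
.csrSymbols <- function(csr) {
  nPer <- diff(csr$ptr)
  sym <- integer(csr$T)
  one <- which(nPer == 1L)
  sym[one] <- csr$spk[csr$ptr[one] + 1L] + 1L
  multi <- which(nPer > 1L)
  if (length(multi)) {
    pick <- csr$ptr[multi] + 1L +
      floor(stats::runif(length(multi)) * nPer[multi])
    sym[multi] <- csr$spk[pick] + 1L
  }
  sym
}

# rebuild period tables from a label run-length encoding
.periodsFromLabels <- function(labels, binWidth) {
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(state = r$values, t0 = starts * binWidth,
             t1 = ends * binWidth,
             duration = r$lengths * binWidth)
}

#' Decode HMM posteriors into a state sequence
#'
#' A bin is assigned the state with the largest posterior when that
#' posterior reaches the threshold (default 0.8); otherwise it is the null
#' state S0 (label 0). S0 periods immediately preceded and followed by
#' periods in the same state are then reattributed to that state; the raw
#' (pre-reattribution) period tiling is kept alongside.
#'
#' @param x an \linkS4class{HMMFit} or a T x K posterior matrix.
#' @param threshold posterior threshold.
#' @param binWidth bin width (ms); taken from the fit when available.
#' @return A \linkS4class{StateSequence}.
#' @export
decodeStates <- function(x, threshold = 0.8, binWidth = NULL) {
  if (is(x, "HMMFit")) {
    post <- x@posteriors
    if (is.null(binWidth)) binWidth <- x@binWidth
  } else {
    post <- x
    if (is.null(binWidth)) binWidth <- 0.5
  }
  idx <- max.col(post, ties.method = "first")
  mx <- post[cbind(seq_len(nrow(post)), idx)]
  labels <- ifelse(mx >= threshold, idx, 0L)
  rawPeriods <- .periodsFromLabels(labels, binWidth)
  # S0 reattribution
  r <- rle(as.integer(labels))
  v <- r$values
  n <- length(v)
  if (n >= 3) {
    inner <- which(v == 0L)
    inner <- inner[inner > 1 & inner < n]
    fix <- inner[v[inner - 1] == v[inner + 1] & v[inner - 1] != 0L]
    v[fix] <- v[fix - 1]
  }
  labels2 <- inverse.rle(list(lengths = r$lengths, values = v))
  periods <- .periodsFromLabels(labels2, binWidth)
  new("StateSequence", labels = as.integer(labels2), binWidth = binWidth,
      periods = periods, rawPeriods = rawPeriods)
}

#' State-period duration statistics
#'
#' Pools the durations of all periods across the HMM states (S0 excluded),
#' drops periods longer than \code{maxPeriod}, and computes the empirical
#' duration distribution p(d), the time-weighted distribution
#' p_t(d) = p(d) d / sum(p(u) u) (the proportion of time spent in periods
#' of duration d), the median duration, and the Kolmogorov-Smirnov distance
#' of log-durations to a fitted normal (distance to log-normality, an
#' over-representation measure for short states).
#'
#' @param seq a \linkS4class{StateSequence} (or a data.frame of periods with
#'   a \code{duration} column).
#' @param maxPeriod exclusion bound (ms).
#' @param raw use the pre-reattribution periods.
#' @param states states to pool (default all non-null states; use \code{0}
#'   for S0-period statistics).
#' @return list(durations, unique, p, pt, medianDuration, ptMedian,
#'   ksLognormal, n, degenerate).
#' @export
durationStatistics <- function(seq, maxPeriod = 3e5, raw = FALSE,
                               states = NULL) {
  per <- if (is.data.frame(seq)) seq else statePeriods(seq, raw = raw)
  if (is.null(states)) per <- per[per$state > 0, , drop = FALSE]
  else per <- per[per$state %in% states, , drop = FALSE]
  d <- per$duration
  d <- d[d <= maxPeriod]
  n <- length(d)
  if (n < 1) stop("no state periods")
  degenerate <- n < 10 || length(unique(d)) < 2
  ud <- sort(unique(d))
  p <- as.numeric(table(factor(d, levels = ud))) / n
  pt <- p * ud / sum(p * ud)
  ks <- if (!degenerate) {
    ld <- log(d)
    suppressWarnings(stats::ks.test(ld, "pnorm", mean(ld),
                                    stats::sd(ld))$statistic)
  } else NA_real_
  # median of the time-weighted distribution
  cum <- cumsum(pt)
  ptMedian <- ud[which(cum >= 0.5)[1]]
  list(durations = d, unique = ud, p = p, pt = pt,
       medianDuration = stats::median(d), ptMedian = ptMedian,
       ksLognormal = unname(ks), n = n, degenerate = degenerate)
}

#' State geometry in neural activity space
#'
#' Per-neuron firing rates are estimated by convolving spiking with a
#' normalized Gaussian kernel (sd 100 ms), evaluated on a coarser grid
#' (default 10 ms; the 100-ms kernel makes finer evaluation redundant),
#' centred and standardized. Neurons with mean rate below \code{minRate}
#' (0.5 Hz) are removed. Per-state centroids are temporal averages of the
#' standardized rates over the state's bins; the separation measure is the
#' mean pairwise Euclidean distance between centroids, and a PCA of the
#' standardized rate matrix is returned for visualization.
#'
#' @param x a \linkS4class{PopulationRaster} or \linkS4class{SimResult}.
#' @param seq the decoded \linkS4class{StateSequence} on the same record.
#' @param sigma Gaussian kernel sd (ms).
#' @param minRate inclusion threshold (Hz).
#' @param evalBin evaluation grid (ms).
#' @param minStateBins states with fewer decoded fine bins are excluded
#'   from the distance average.
#' @return list(centroids, meanPairwiseDistance, pca, stateAtEval,
#'   keptNeurons).
#' @export
stateGeometry <- function(x, seq, sigma = 100, minRate = 0.5,
                          evalBin = 10, minStateBins = 100) {
  csr <- .toCSR(x)
  binW <- csr$binWidth
  duration <- csr$T * binW
  nEval <- floor(duration / evalBin)
  # counts on the evaluation grid
  bins <- rep.int(seq_len(csr$T), diff(csr$ptr))
  ev <- pmin(ceiling(bins * binW / evalBin), nEval)
  cnt <- as.matrix(Matrix::sparseMatrix(i = csr$spk + 1L, j = ev, x = 1,
                                        dims = c(csr$nNeurons, nEval)))
  rate <- cnt * (1000 / evalBin)
  meanRate <- rowMeans(rate)
  keep <- meanRate >= minRate
  if (!any(keep)) stop("no neuron reaches the minimum rate")
  rate <- rate[keep, , drop = FALSE]
  # Gaussian smoothing along time
  half <- ceiling(4 * sigma / evalBin)
  kern <- stats::dnorm(seq(-half, half) * evalBin, 0, sigma)
  kern <- kern / sum(kern)
  sm <- t(apply(rate, 1, function(r)
    stats::filter(c(rep(r[1], half), r, rep(r[length(r)], half)), kern,
                  sides = 2)[(half + 1):(half + length(r))]))
  z <- t(scale(t(sm)))
  z[is.na(z)] <- 0
  # state label at each evaluation bin (fine bin at the center)
  centerFine <- pmin(ceiling(((seq_len(nEval) - 0.5) * evalBin) / binW),
                     length(stateLabels(seq)))
  stEval <- stateLabels(seq)[centerFine]
  states <- sort(unique(stEval[stEval > 0]))
  fineCounts <- tabulate(stateLabels(seq) + 1L)
  okStates <- states[fineCounts[states + 1L] >= minStateBins]
  centroids <- sapply(okStates, function(k)
    rowMeans(z[, stEval == k, drop = FALSE]))
  mpd <- if (length(okStates) >= 2) {
    pr <- utils::combn(seq_along(okStates), 2)
    mean(apply(pr, 2, function(ij)
      sqrt(sum((centroids[, ij[1]] - centroids[, ij[2]])^2))))
  } else NA_real_
  pca <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  list(centroids = centroids, meanPairwiseDistance = mpd, pca = pca,
       stateAtEval = stEval, keptNeurons = which(keep))
}

#' AIC/BIC scan over the number of HMM states
#'
#' Fits the HMM for each state count in \code{nRange} and reports AIC and
#' BIC (parameters: K(K-1) transition + K N emission + K-1 initial).
#'
#' @param x raster or simulation (as \code{\link{fitHMM}}).
#' @param nRange state counts to scan.
#' @param cfg base \code{\link{hmmConfig}}.
#' @param seed integer seed.
#' @return data.frame (n_states, logLik, nParams, AIC, BIC, converged).
#' @export
hmmModelSelection <- function(x, nRange = 2:10, cfg = hmmConfig(),
                              seed = 1) {
  csr <- .toCSR(x, binWidth = cfg$binWidth)
  rows <- lapply(nRange, function(K) {
    cfgK <- cfg; cfgK$nStates <- K
    fit <- tryCatch(fitHMM(x, cfgK, seed = seed),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(n_states = K, logLik = NA, nParams = NA, AIC = NA,
                        BIC = NA, converged = NA))
    np <- K * (K - 1) + K * csr$nNeurons + (K - 1)
    data.frame(n_states = K, logLik = fit@logLik, nParams = np,
               AIC = -2 * fit@logLik + 2 * np,
               BIC = -2 * fit@logLik + np * log(csr$T),
               converged = fit@converged)
  })
  do.call(rbind, rows)
}

#' Shuffled-control raster
#'
#' Randomly shuffles both the timing and the neuron assignment of every
#' spike (total spike count preserved), destroying the temporal structure
#' that supports long metastable states.
#'
#' @param x a \linkS4class{PopulationRaster} or \linkS4class{SimResult}.
#' @param seed integer seed.
#' @return A \linkS4class{PopulationRaster} with sparse counts.
#' @export
shuffleRaster <- function(x, seed = 1) {
  csr <- .toCSR(x)
  nsp <- length(csr$spk)
  withSeed(seed, {
    i <- sample.int(csr$nNeurons, nsp, replace = TRUE)
    j <- sample.int(csr$T, nsp, replace = TRUE)
    counts <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                   dims = c(csr$nNeurons, csr$T))
    new("PopulationRaster", counts = counts, binWidth = csr$binWidth,
        tStart = 0, neuronMeta = data.frame())
  })
}
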