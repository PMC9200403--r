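# Autocorrelogram binning constants: 10/3-ms bins over (0, 1000] ms, first
# 10 ms (3 bins) removed before smoothing and fitting -> 297 analyzed bins.
.AC_BIN <- 10 / 3
.AC_NBINS <- 300L
.AC_DROP <- 3L

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed}, so seeded fits do not disturb the
#' caller's RNG stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Spike-count autocorrelation over 50-ms bins
#'
#' Spike counts are measured in 14 successive 50-ms bins of a 700-ms pre-event
#' window on each trial. For each positive lag k (in bins), the across-trial
#' Pearson correlation is computed between the count vectors of every bin pair
#' (t, t+k) and averaged, giving the correlation R at lag 50k ms. Bin pairs in
#' which either bin has zero variance across trials are skipped with a
#' warning.
#'
#' @param counts integer matrix, trials x 14 bins.
#' @return An \linkS4class{ScAutocorr} with lags 50, 100, ..., 650 ms.
#' @export
spikeCountAutocorrelation <- function(counts) {
  counts <- as.matrix(counts)
  nb <- ncol(counts)
  if (nrow(counts) < 2) stop("need at least 2 trials")
  v <- apply(counts, 2, stats::var)
  r <- rep(NA_real_, nb - 1)
  skipped <- FALSE
  for (k in seq_len(nb - 1)) {
    cc <- numeric(0)
    for (t in seq_len(nb - k)) {
      if (v[t] == 0 || v[t + k] == 0) { skipped <- TRUE; next }
      cc <- c(cc, stats::cor(counts[, t], counts[, t + k]))
    }
    r[k] <- if (length(cc)) mean(cc) else NA_real_
  }
  if (skipped) warning("zero-variance bin(s): some bin pairs skipped")
  new("ScAutocorr", lags = 50 * seq_len(nb - 1), r = r,
      nTrials = nrow(counts))
}

#' Mono-exponential fit with random restarts
#'
#' Fits y ~ A exp(-t / tau) + B by nonlinear least squares
#' (Levenberg-Marquardt, \code{minpack.lm::nlsLM}) from \code{nRestarts}
#' random initial guesses drawn uniformly in [0, 2(max(y) - min(y))] for A,
#' [0, 2 min(y)] for B and [0, 1000] ms for tau; the fit with the lowest
#' residual sum of squares is kept. Validity requires positive A, B and tau
#' (the 1000 ms range bounds the initial guesses, not the estimate).
#'
#' @param x,y data (x in ms).
#' @param nRestarts number of random initializations.
#' @param seed optional seed for the restarts (restores the caller's RNG).
#' @param kind fit label ("GLOBAL", "FAST" or "SLOW").
#' @return An \linkS4class{ExpFit}; never throws on non-convergence (an
#'   invalid fit is returned when every restart fails).
#' @export
fitExpRestarts <- function(x, y, nRestarts = 50, seed = NULL, kind = "GLOBAL") {
  stopifnot(length(x) == length(y))
  if (length(x) < 4 || all(!is.finite(y)))
    return(new("ExpFit", kind = kind, valid = FALSE))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  rng <- max(y) - min(y)
  if (rng <= 0) return(new("ExpFit", kind = kind, valid = FALSE))
  inits <- withSeed(seed, data.frame(
    A = stats::runif(nRestarts, 0, 2 * rng),
    B = stats::runif(nRestarts, 0, 2 * max(min(y), 0)),
    tau = stats::runif(nRestarts, 0, 1000)))
  best <- NULL; bestRss <- Inf
  for (i in seq_len(nRestarts)) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      y ~ A * exp(-x / tau) + B,
      start = list(A = inits$A[i], B = inits$B[i],
                   tau = max(inits$tau[i], 1e-3)),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.finite(rss) && rss < bestRss) { bestRss <- rss; best <- fit }
  }
  if (is.null(best)) return(new("ExpFit", kind = kind, valid = FALSE))
  cf <- stats::coef(best)
  valid <- isTRUE(cf["A"] > 0 && cf["B"] > 0 && cf["tau"] > 0)
  new("ExpFit", A = unname(cf["A"]), B = unname(cf["B"]),
      tau = unname(cf["tau"]), rmse = sqrt(bestRss / length(x)),
      kind = kind, valid = valid)
}

#' Fit the spike-count timescale scTAU
#'
#' Fits R ~ A exp(-t / scTAU) + B to the positive-lag spike-count
#' autocorrelation, either of a single unit or pooled over a population (all
#' units' lag points stacked, as for a population-level fit).
#'
#' @param ac an \linkS4class{ScAutocorr} or a list of them (pooled fit).
#' @param nRestarts,seed passed to \code{\link{fitExpRestarts}}.
#' @return An \linkS4class{ExpFit}; flagged invalid when the fit does not
#'   converge or the autocorrelation is degenerate (constant R).
#' @export
fitScTau <- function(ac, nRestarts = 50, seed = NULL) {
  if (is(ac, "ScAutocorr")) ac <- list(ac)
  x <- unlist(lapply(ac, function(a) a@lags))
  y <- unlist(lapply(ac, function(a) a@r))
  ok <- is.finite(y)
  if (sum(ok) < 4) return(new("ExpFit", valid = FALSE))
  fitExpRestarts(x[ok], y[ok], nRestarts = nRestarts, seed = seed,
                 kind = "GLOBAL")
}

#' Lagged spike-time differences up to a maximum order
#'
#' Forward differences t[i+k] - t[i] for k = 1..maxOrder, excluding pairs
#' that span different intervals of a restricted train.
#' @noRd
laggedDifferences <- function(train, maxOrder = 100, maxLag = 1000) {
  ts <- spikeTimes(train)
  n <- length(ts)
  if (n < 2) return(numeric(0))
  iv <- trainIntervals(train)
  id <- if (nrow(iv) > 1) findInterval(ts, iv[, 1]) else rep(1L, n)
  out <- vector("list", maxOrder)
  for (k in seq_len(min(maxOrder, n - 1))) {
    d <- ts[(k + 1):n] - ts[1:(n - k)]
    same <- id[(k + 1):n] == id[1:(n - k)]
    d <- d[same & d > 0 & d <= maxLag]
    out[[k]] <- d
  }
  unlist(out)
}

#' Spike-time autocorrelogram of a unit
#'
#' Computes all forward lagged differences between spike times up to the
#' 100th order (within single intervals of a restricted train), histograms
#' them in 10/3-ms bins over (0, 1000] ms, converts the counts to a density
#' normalized to peak at 1 over the analyzed range, removes the first 10 ms
#' (to eliminate contamination below the absolute refractory period) and
#' smooths the remainder by loess (local quadratic regression, span 0.1) to
#' filter high-frequency noise before peak detection.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param minSpikes minimum spike count required for a stable estimate
#'   (default 1000).
#' @param span loess span.
#' @return A \linkS4class{SpikeAutocorr}, or an error when the train has too
#'   few spikes.
#' @export
spikeAutocorrelogram <- function(train, minSpikes = 1000, span = 0.1) {
  ts <- spikeTimes(train)
  if (length(ts) < minSpikes)
    stop("unit '", unitId(train), "' has ", length(ts),
         " spikes (< ", minSpikes, "); excluded")
  d <- laggedDifferences(train)
  cnt <- tabulate(pmin(ceiling(d / .AC_BIN), .AC_NBINS), nbins = .AC_NBINS)
  keep <- (.AC_DROP + 1L):.AC_NBINS
  centers <- (keep - 0.5) * .AC_BIN
  dens <- cnt[keep] / sum(cnt)            # probability mass over lag bins
  if (max(dens) > 0) dens <- dens / max(dens)  # peak-at-1 normalization
  lo <- stats::loess(dens ~ centers, span = span, degree = 2,
                     family = "gaussian")
  sm <- stats::predict(lo, centers)
  new("SpikeAutocorr", binCenters = centers, density = dens, smoothed = sm,
      nSpikes = length(ts))
}

#' Locate the peak, dip and second peak of an autocorrelogram
#'
#' The peak is the maximum of the smoothed AC, except when the maximum is the
#' very first analyzed bin, in which case the peak is the first local maximum
#' after the first bin (flagged degenerate when no such local maximum
#' exists). A dip is detected when the first local minimum within 100 ms
#' after the peak descends below \code{min + dipFraction * (max - min)} of
#' the smoothed AC's global range; the second peak is then the maximum of the
#' AC after the dip. Local extrema use strict inequality over a one-bin
#' neighbourhood, plateau ties broken toward the earlier bin.
#'
#' @param ac a \linkS4class{SpikeAutocorr}.
#' @param dipFraction dip threshold as a fraction of the global range above
#'   the minimum (default 0.75; 0.25 gives the stricter alternative reading).
#' @return list(peakIndex, lat, dip = c(index, value) or NULL,
#'   secondPeak or NULL, degenerate).
#' @export
findAcPeaks <- function(ac, dipFraction = 0.75) {
  y <- ac@smoothed
  n <- length(y)
  degenerate <- FALSE
  localMax <- which(diff(sign(diff(y))) < 0) + 1  # strict one-bin local maxima
  peak <- which.max(y)
  if (peak == 1) {
    cand <- localMax[localMax > 1]
    if (length(cand)) peak <- cand[1]
    else degenerate <- TRUE  # monotone decreasing AC
  }
  dip <- NULL; secondPeak <- NULL
  searchEnd <- min(n, peak + ceiling(100 / .AC_BIN))
  if (peak < searchEnd - 1) {
    seg <- y[peak:searchEnd]
    localMin <- which(diff(sign(diff(seg))) > 0) + 1
    if (length(localMin)) {
      di <- peak + localMin[1] - 1
      thr <- min(y) + dipFraction * (max(y) - min(y))
      if (y[di] < thr) {
        dip <- c(index = di, value = y[di])
        after <- (di + 1):n
        secondPeak <- after[which.max(y[after])]
      }
    }
  }
  list(peakIndex = peak, lat = ac@binCenters[peak], dip = dip,
       secondPeak = secondPeak, degenerate = degenerate)
}

#' Fit one exponential segment of an autocorrelogram
#'
#' @param ac a \linkS4class{SpikeAutocorr}.
#' @param startIndex,endIndex analyzed-bin indices bounding the segment
#'   (inclusive).
#' @param nRestarts,seed,kind passed to \code{\link{fitExpRestarts}}.
#' @return An \linkS4class{ExpFit}.
#' @export
fitExponentialSegment <- function(ac, startIndex, endIndex = length(ac@smoothed),
                                  nRestarts = 50, seed = NULL,
                                  kind = "GLOBAL") {
  idx <- startIndex:endIndex
  if (length(idx) < 4) return(new("ExpFit", kind = kind, valid = FALSE))
  fitExpRestarts(ac@binCenters[idx], ac@smoothed[idx],
                 nRestarts = nRestarts, seed = seed, kind = kind)
}

#' Extract the temporal signature (LAT, TAU) of a unit
#'
#' Full pipeline: spike autocorrelogram, peak/dip detection, GLOBAL
#' mono-exponential fit from the peak to the end of the AC. When a dip is
#' present, FAST (peak to dip) and SLOW (second peak to end) fits are
#' additionally computed purely as a quality check: the GLOBAL fit is kept
#' when at least one of them is invalid, or when its RMSE is below the sum of
#' the valid FAST and SLOW RMSEs. Units without a (kept) valid GLOBAL fit are
#' returned as exclusion records.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param minSpikes minimum spike count (default 1000).
#' @param nRestarts random fit restarts.
#' @param seed seed for the restarts.
#' @param dipFraction see \code{\link{findAcPeaks}}.
#' @param computeIsiLatency also compute \code{\link{firstOrderLatency}}.
#' @return A \linkS4class{TemporalSignature}.
#' @export
extractSignature <- function(train, minSpikes = 1000, nRestarts = 50,
                             seed = NULL, dipFraction = 0.75,
                             computeIsiLatency = FALSE) {
  excl <- function(reason) new("TemporalSignature", unitId = unitId(train),
                               lat = NA_real_, tau = NA_real_,
                               peakIndex = NA_real_, valid = FALSE,
                               reason = reason,
                               nSpikes = length(spikeTimes(train)))
  ac <- tryCatch(spikeAutocorrelogram(train, minSpikes = minSpikes),
                 error = function(e) NULL)
  if (is.null(ac)) return(excl(sprintf("fewer than %d spikes", minSpikes)))
  pk <- findAcPeaks(ac, dipFraction = dipFraction)
  glob <- fitExponentialSegment(ac, pk$peakIndex, seed = seed,
                                nRestarts = nRestarts, kind = "GLOBAL")
  if (!isValid(glob)) return(excl("no valid GLOBAL fit"))
  keep <- TRUE
  if (!is.null(pk$dip)) {
    fast <- fitExponentialSegment(ac, pk$peakIndex, pk$dip[["index"]],
                                  seed = seed, nRestarts = nRestarts,
                                  kind = "FAST")
    slow <- fitExponentialSegment(ac, pk$secondPeak, seed = seed,
                                  nRestarts = nRestarts, kind = "SLOW")
    if (isValid(fast) && isValid(slow))
      keep <- glob@rmse < (fast@rmse + slow@rmse)
  }
  if (!keep) return(excl("GLOBAL fit outperformed by FAST+SLOW"))
  iv <- trainIntervals(train)
  totalTime <- sum(iv[, 2] - iv[, 1])
  fol <- if (computeIsiLatency)
    tryCatch(firstOrderLatency(train), error = function(e) NA_real_)
  else NA_real_
  new("TemporalSignature", unitId = unitId(train), lat = pk$lat,
      tau = tauValue(glob), fit = glob, peakIndex = pk$peakIndex,
      dip = pk$dip, secondPeak = pk$secondPeak, firstOrderLatency = fol,
      valid = TRUE, nSpikes = ac@nSpikes,
      meanRate = if (totalTime > 0) 1000 * ac@nSpikes / totalTime else NA_real_)
}

#' First-order latency: the latency of the ISI distribution
#'
#' Builds the inter-spike-interval histogram with the same 10/3-ms binning,
#' first-10-ms removal and loess smoothing as the autocorrelogram, and
#' returns the lag of its peak (the mode of the smoothed ISI distribution).
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param span loess span.
#' @return Latency in ms; errors when fewer than 100 ISIs are available.
#' @export
firstOrderLatency <- function(train, span = 0.1) {
  ts <- spikeTimes(train)
  iv <- trainIntervals(train)
  id <- if (nrow(iv) > 1) findInterval(ts, iv[, 1]) else rep(1L, length(ts))
  isi <- diff(ts)
  isi <- isi[id[-1] == id[-length(id)]]
  isi <- isi[isi > 0 & isi <= 1000]
  if (length(isi) < 100) stop("fewer than 100 ISIs")
  cnt <- tabulate(pmin(ceiling(isi / .AC_BIN), .AC_NBINS), nbins = .AC_NBINS)
  keep <- (.AC_DROP + 1L):.AC_NBINS
  centers <- (keep - 0.5) * .AC_BIN
  dens <- cnt[keep] / sum(cnt)
  lo <- stats::loess(dens ~ centers, span = span, degree = 2)
  sm <- stats::predict(lo, centers)
  centers[which.max(sm)]
}

#' Tabulate temporal signatures
#'
#' @param signatures list of \linkS4class{TemporalSignature}.
#' @param trains optional matching list of \linkS4class{SpikeTrain} supplying
#'   area / cell-type metadata.
#' @return data.frame with columns unit_id, area, cell_type, LAT_ms, TAU_ms,
#'   A, B, rmse, valid, scTAU_ms, n_spikes.
#' @export
signatureTable <- function(signatures, trains = NULL) {
  df <- do.call(rbind, lapply(seq_along(signatures), function(i) {
    s <- signatures[[i]]
    data.frame(unit_id = s@unitId,
               area = if (!is.null(trains)) trains[[i]]@area else NA,
               cell_type = if (!is.null(trains)) trains[[i]]@cellType else NA,
               LAT_ms = s@lat, TAU_ms = s@tau, A = s@fit@A, B = s@fit@B,
               rmse = s@fit@rmse, valid = s@valid, scTAU_ms = s@scTau,
               n_spikes = s@nSpikes)
  }))
  df
}
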