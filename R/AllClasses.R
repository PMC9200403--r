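#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importFrom Matrix sparseMatrix
#' @importClassesFrom Matrix sparseMatrix
#' @importFrom stats runif rnorm rpois rexp rgamma rlnorm
#' @useDynLib SpikeDynamics, .registration = TRUE
NULL

#' SpikeTrain: spike times of one unit
#'
#' The atomic input of the temporal-signature pipeline: the spike times of a
#' single unit, in milliseconds, with recording bounds and optional metadata
#' (cortical area, putative cell type, antero-posterior position).
#'
#' When a train has been restricted to a set of intervals (engage/pause
#' segments), the \code{intervals} slot carries the interval structure so that
#' downstream lagged differences are computed within single intervals only and
#' never span a gap.
#'
#' @slot unitId character identifier.
#' @slot times numeric, strictly increasing spike times (ms).
#' @slot tStart,tStop numeric recording bounds (ms).
#' @slot area character, one of "MCC", "LPFC", "other".
#' @slot cellType character, one of "FS", "RS", "unknown".
#' @slot apPosition numeric antero-posterior coordinate (mm) or NA.
#' @slot intervals numeric matrix with columns t0, t1: the half-open intervals
#'   the train is defined on (a single row spanning the record for an
#'   unrestricted train).
#' @export
setClass("SpikeTrain",
  representation(
    unitId = "character", times = "numeric",
    tStart = "numeric", tStop = "numeric",
    area = "character", cellType = "character", apPosition = "numeric",
    intervals = "matrix"
  ),
  prototype(
    area = "other", cellType = "unknown", apPosition = NA_real_
  )
)

setValidity("SpikeTrain", function(object) {
  msg <- character()
  ts <- object@times
  if (length(ts) && any(!is.finite(ts))) msg <- c(msg, "non-finite spike times")
  if (length(ts) > 1 && any(diff(ts) <= 0))
    msg <- c(msg, sprintf("spike times of unit '%s' not strictly increasing", object@unitId))
  if (length(ts)) {
    if (ts[1] < object@tStart) msg <- c(msg, "first spike before tStart")
    if (ts[length(ts)] > object@tStop) msg <- c(msg, "last spike after tStop")
  }
  if (object@tStop < object@tStart) msg <- c(msg, "tStop < tStart")
  if (!object@area %in% c("MCC", "LPFC", "other")) msg <- c(msg, "unknown area")
  if (!object@cellType %in% c("FS", "RS", "unknown")) msg <- c(msg, "unknown cellType")
  if (ncol(object@intervals) != 2) msg <- c(msg, "intervals must have two columns")
  if (length(msg)) msg else TRUE
})

#' Construct a SpikeTrain
#'
#' @param times spike times in ms, strictly increasing.
#' @param tStart,tStop recording bounds in ms; default to the span of
#'   \code{times} (0 when empty).
#' @param unitId unit identifier.
#' @param area,cellType,apPosition optional metadata.
#' @param intervals optional two-column matrix of half-open intervals (ms);
#'   defaults to the single interval \code{[tStart, tStop)}.
#' @return A \linkS4class{SpikeTrain}.
#' @export
SpikeTrain <- function(times, tStart = if (length(times)) min(times) else 0,
                       tStop = if (length(times)) max(times) else 0,
                       unitId = "u", area = "other", cellType = "unknown",
                       apPosition = NA_real_, intervals = NULL) {
  if (is.null(intervals))
    intervals <- matrix(c(tStart, tStop), ncol = 2,
                        dimnames = list(NULL, c("t0", "t1")))
  new("SpikeTrain", unitId = as.character(unitId), times = as.numeric(times),
      tStart = as.numeric(tStart), tStop = as.numeric(tStop),
      area = area, cellType = cellType, apPosition = apPosition,
      intervals = intervals)
}

#' PopulationRaster: binned spike counts of a neuron population
#'
#' Counts are stored as a dense base matrix for small rasters or a
#' \pkg{Matrix} sparse matrix for long fine-binned records (0.5-ms bins over
#' hundreds of seconds), where a dense representation would not fit in
#' memory.
#'
#' @slot counts matrix or sparseMatrix, neurons x bins, non-negative
#'   integers.
#' @slot binWidth numeric bin width (ms).
#' @slot tStart numeric left edge of the first bin (ms).
#' @slot neuronMeta data.frame with one row per neuron (area, cellType, ...).
#' @export
setClass("PopulationRaster",
  representation(counts = "ANY", binWidth = "numeric", tStart = "numeric",
                 neuronMeta = "data.frame"))

setValidity("PopulationRaster", function(object) {
  msg <- character()
  vals <- if (is(object@counts, "sparseMatrix")) object@counts@x
          else object@counts
  if (length(vals)) {
    if (any(vals < 0)) msg <- c(msg, "negative counts")
    if (any(vals != round(vals))) msg <- c(msg, "non-integer counts")
  }
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be positive")
  if (nrow(object@neuronMeta) &&
      nrow(object@neuronMeta) != nrow(object@counts))
    msg <- c(msg, "neuronMeta rows must match neurons")
  if (length(msg)) msg else TRUE
})

#' IntervalSet: labelled half-open time intervals
#'
#' @slot t0,t1 numeric interval bounds (ms), disjoint and sorted.
#' @slot label character per interval: "engage", "pause" or "custom".
#' @slot firstPauseStart numeric, start of the first pause (ms) or NA; kept
#'   for the time-on-task control that compares engage periods occurring
#'   after the first pause.
#' @export
setClass("IntervalSet",
  representation(t0 = "numeric", t1 = "numeric", label = "character",
                 firstPauseStart = "numeric"),
  prototype(firstPauseStart = NA_real_))

setValidity("IntervalSet", function(object) {
  msg <- character()
  if (length(object@t0) != length(object@t1) ||
      length(object@t0) != length(object@label))
    msg <- c(msg, "t0, t1, label lengths differ")
  if (any(object@t1 <= object@t0)) msg <- c(msg, "intervals must have t1 > t0")
  n <- length(object@t0)
  if (n > 1 && any(object@t0[-1] < object@t1[-n]))
    msg <- c(msg, "intervals must be disjoint and sorted")
  if (length(msg)) msg else TRUE
})

#' @rdname IntervalSet-class
#' @param t0,t1 interval bounds (ms).
#' @param label per-interval labels.
#' @param firstPauseStart see slot documentation.
#' @export
IntervalSet <- function(t0, t1, label = rep("custom", length(t0)),
                        firstPauseStart = NA_real_) {
  new("IntervalSet", t0 = as.numeric(t0), t1 = as.numeric(t1),
      label = as.character(label), firstPauseStart = firstPauseStart)
}

#' TrialEvents: per-trial task event table
#'
#' Wraps a data.frame with one row per trial and columns trialStart, cueOnset,
#' feedbackOnset, trialEnd (ms), choice ("work"/"check"), feedback
#' ("reward"/"noreward"), gaugeStep (1-7) and blockSpeed ("fast"/"slow").
#'
#' @slot trials data.frame as described above, ordered by trialStart.
#' @export
setClass("TrialEvents", representation(trials = "data.frame"))

setValidity("TrialEvents", function(object) {
  tr <- object@trials
  need <- c("trialStart", "cueOnset", "feedbackOnset", "trialEnd")
  msg <- character()
  if (!all(need %in% names(tr))) msg <- c(msg, "missing event columns")
  else {
    if (is.unsorted(tr$trialStart)) msg <- c(msg, "trials must be ordered")
    bad <- with(tr, trialStart > cueOnset | cueOnset > feedbackOnset |
                  feedbackOnset > trialEnd)
    if (any(bad)) msg <- c(msg, "events out of order within trial")
    if (nrow(tr) > 1 && any(tr$trialStart[-1] < tr$trialEnd[-nrow(tr)]))
      msg <- c(msg, "trials overlap")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname TrialEvents-class
#' @param trials data.frame of trial events (ms).
#' @export
TrialEvents <- function(trials) new("TrialEvents", trials = trials)

#' ExpFit: one mono-exponential fit A exp(-t/tau) + B of an autocorrelogram
#'
#' A fit is valid iff A, B and tau are all positive (tau additionally bounded
#' by the 1000 ms search range).
#'
#' @slot A,B,tau fitted amplitude, offset and time constant (ms).
#' @slot rmse root-mean-square error of the fit.
#' @slot kind "GLOBAL", "FAST" or "SLOW".
#' @slot valid logical.
#' @export
setClass("ExpFit",
  representation(A = "numeric", B = "numeric", tau = "numeric",
                 rmse = "numeric", kind = "character", valid = "logical"),
  prototype(A = NA_real_, B = NA_real_, tau = NA_real_, rmse = NA_real_,
            kind = "GLOBAL", valid = FALSE))

#' TemporalSignature: the (LAT, TAU) signature of one unit
#'
#' @slot unitId character.
#' @slot lat autocorrelogram peak latency (ms).
#' @slot tau time constant of the GLOBAL exponential fit (ms).
#' @slot fit the GLOBAL \linkS4class{ExpFit}.
#' @slot peakIndex index of the selected peak bin in the analyzed AC.
#' @slot dip numeric c(index, value) of a detected dip, or NULL.
#' @slot secondPeak index of the post-dip peak, or NULL.
#' @slot firstOrderLatency latency of the ISI distribution (ms) or NA.
#' @slot scTau spike-count timescale (ms) or NA.
#' @slot valid logical: whether a valid GLOBAL fit was obtained.
#' @slot reason character: exclusion reason when not valid.
#' @slot nSpikes number of spikes used.
#' @slot meanRate mean firing rate (Hz).
#' @export
setClass("TemporalSignature",
  representation(unitId = "character", lat = "numeric", tau = "numeric",
                 fit = "ExpFit", peakIndex = "numeric", dip = "ANY",
                 secondPeak = "ANY", firstOrderLatency = "numeric",
                 scTau = "numeric", valid = "logical", reason = "character",
                 nSpikes = "numeric", meanRate = "numeric"),
  prototype(dip = NULL, secondPeak = NULL, firstOrderLatency = NA_real_,
            scTau = NA_real_, valid = FALSE, reason = "", nSpikes = 0,
            meanRate = NA_real_))

#' ScAutocorr: spike-count autocorrelation over 50-ms lags
#'
#' @slot lags numeric lag values (multiples of 50 ms).
#' @slot r numeric mean across-trial correlation per lag.
#' @slot nTrials number of trials used.
#' @export
setClass("ScAutocorr",
  representation(lags = "numeric", r = "numeric", nTrials = "numeric"))

#' SpikeAutocorr: spike-time autocorrelogram in 3.33-ms bins
#'
#' Lagged spike-time differences up to the 100th order, histogrammed in
#' 10/3-ms bins over (0, 1000] ms, converted to a density normalized to peak
#' at 1, with the first 10 ms removed and a loess-smoothed copy.
#'
#' @slot binCenters numeric centers of the analyzed bins (ms).
#' @slot density numeric raw normalized density.
#' @slot smoothed numeric loess-smoothed density.
#' @slot nSpikes number of spikes in the train.
#' @export
setClass("SpikeAutocorr",
  representation(binCenters = "numeric", density = "numeric",
                 smoothed = "numeric", nSpikes = "numeric"))

#' ParamSet: named parameter collections
#'
#' Base class for cellular, background and network parameter sets. Parameters
#' are accessed with \code{$} or \code{param()}; validity requires the full
#' expected name set, so misspelled or missing parameters fail early.
#'
#' @slot values named list of numeric parameters.
#' @export
setClass("ParamSet", representation(values = "list"))

#' @rdname ParamSet-class
#' @export
setClass("CellularParams", contains = "ParamSet")

#' @rdname ParamSet-class
#' @export
setClass("OUBackgroundParams", contains = "ParamSet")

#' @rdname ParamSet-class
#' @export
setClass("NetworkParams", contains = "ParamSet")

#' SynapticMatrix: realized connectivity of a network instance
#'
#' @slot weights numeric matrix w(i, j) (pre x post), zero where no
#'   connection; no autapses.
#' @slot isExc logical per neuron.
#' @slot gGABAA,gGABAB numeric per-postsynaptic balanced maximal conductances.
#' @slot seed integer seed used for the draw.
#' @export
setClass("SynapticMatrix",
  representation(weights = "matrix", isExc = "logical",
                 gGABAA = "numeric", gGABAB = "numeric", seed = "numeric"))

setValidity("SynapticMatrix", function(object) {
  msg <- character()
  if (any(diag(object@weights) != 0)) msg <- c(msg, "autapses present")
  if (any(object@weights < 0)) msg <- c(msg, "negative weights")
  if (length(object@isExc) != nrow(object@weights))
    msg <- c(msg, "isExc length mismatch")
  if (length(msg)) msg else TRUE
})

#' SimResult: raster and state snapshots of a network simulation
#'
#' @slot spikes data.frame with columns neuron (1-based index) and time (ms).
#' @slot nNeurons number of neurons.
#' @slot isExc logical per neuron.
#' @slot duration simulated duration (ms).
#' @slot dt integration step (ms).
#' @slot snapshots list of full dynamical-state snapshots (named by time);
#'   each restores the simulation bit-identically.
#' @slot seed integer.
#' @export
setClass("SimResult",
  representation(spikes = "data.frame", nNeurons = "numeric",
                 isExc = "logical", duration = "numeric", dt = "numeric",
                 snapshots = "list", seed = "numeric"))

#' HMMFit: an EM-trained hidden Markov model of population spiking
#'
#' @slot transition K x K transition matrix.
#' @slot emission K x N per-state Bernoulli spike probabilities per bin.
#' @slot initProb length-K initial state distribution.
#' @slot logLik log-likelihood of the best restart.
#' @slot posteriors T x K posterior state probabilities.
#' @slot binWidth bin width of the fitted raster (ms).
#' @slot emissionType "bernoulli" (independent per-neuron spike
#'   probabilities) or "multinomial" (one symbol per bin: the identity of
#'   the spiking neuron, ties broken at random, 0 for silence).
#' @slot converged logical.
#' @export
setClass("HMMFit",
  representation(transition = "matrix", emission = "matrix",
                 initProb = "numeric", logLik = "numeric",
                 posteriors = "matrix", binWidth = "numeric",
                 emissionType = "character", converged = "logical"),
  prototype(emissionType = "bernoulli"))

#' StateSequence: decoded per-bin HMM state labels
#'
#' State 0 is the null state S0 (no posterior above threshold). \code{periods}
#' holds the final period tiling after S0 reattribution; \code{rawPeriods} the
#' tiling before reattribution (used e.g. for S0 period-duration statistics).
#'
#' @slot labels integer per-bin state labels (0 = S0).
#' @slot binWidth numeric (ms).
#' @slot periods data.frame (state, t0, t1, duration) after reattribution.
#' @slot rawPeriods data.frame before S0 reattribution.
#' @export
setClass("StateSequence",
  representation(labels = "integer", binWidth = "numeric",
                 periods = "data.frame", rawPeriods = "data.frame"))

#' SignatureDensity: bivariate KDE of (TAU, LAT) signatures
#'
#' @slot tauGrid,latGrid grid coordinates (ms).
#' @slot density matrix of density values (tau x lat), integrating to 1.
#' @slot bandwidth numeric c(tau, lat) bandwidths.
#' @slot tag character population tag.
#' @export
setClass("SignatureDensity",
  representation(tauGrid = "numeric", latGrid = "numeric",
                 density = "matrix", bandwidth = "numeric", tag = "character"),
  prototype(tag = ""))

setValidity("SignatureDensity", function(object) {
  if (any(object@density < 0)) "negative density values" else TRUE
})
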