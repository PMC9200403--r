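#' Accessors
#'
#' Small accessor generics for the package's classes. Slots are never meant to
#' be reached with \code{@} by users.
#'
#' @param x an object.
#' @param name parameter name (for \code{$} on \linkS4class{ParamSet}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)

#' @rdname accessors
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))
#' @rdname accessors
#' @export
setMethod("unitId", "SpikeTrain", function(x) x@unitId)

#' @rdname accessors
#' @export
setGeneric("recordingBounds", function(x) standardGeneric("recordingBounds"))
#' @rdname accessors
#' @export
setMethod("recordingBounds", "SpikeTrain", function(x) c(x@tStart, x@tStop))

#' @rdname accessors
#' @export
setGeneric("trainIntervals", function(x) standardGeneric("trainIntervals"))
#' @rdname accessors
#' @export
setMethod("trainIntervals", "SpikeTrain", function(x) x@intervals)

#' @rdname accessors
#' @export
setGeneric("rasterCounts", function(x) standardGeneric("rasterCounts"))
#' @rdname accessors
#' @export
setMethod("rasterCounts", "PopulationRaster", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setMethod("binWidth", "PopulationRaster", function(x) x@binWidth)
#' @rdname accessors
#' @export
setMethod("binWidth", "StateSequence", function(x) x@binWidth)

#' @rdname accessors
#' @export
setGeneric("neuronMeta", function(x) standardGeneric("neuronMeta"))
#' @rdname accessors
#' @export
setMethod("neuronMeta", "PopulationRaster", function(x) x@neuronMeta)

#' @rdname accessors
#' @export
setGeneric("intervalTable", function(x) standardGeneric("intervalTable"))
#' @rdname accessors
#' @export
setMethod("intervalTable", "IntervalSet", function(x)
  data.frame(t0 = x@t0, t1 = x@t1, label = x@label))

#' @rdname accessors
#' @export
setGeneric("firstPauseStart", function(x) standardGeneric("firstPauseStart"))
#' @rdname accessors
#' @export
setMethod("firstPauseStart", "IntervalSet", function(x) x@firstPauseStart)

#' @rdname accessors
#' @export
setGeneric("trialTable", function(x) standardGeneric("trialTable"))
#' @rdname accessors
#' @export
setMethod("trialTable", "TrialEvents", function(x) x@trials)

#' @rdname accessors
#' @export
setGeneric("tauValue", function(x) standardGeneric("tauValue"))
#' @rdname accessors
#' @export
setMethod("tauValue", "TemporalSignature", function(x) x@tau)
#' @rdname accessors
#' @export
setMethod("tauValue", "ExpFit", function(x) x@tau)

#' @rdname accessors
#' @export
setGeneric("latValue", function(x) standardGeneric("latValue"))
#' @rdname accessors
#' @export
setMethod("latValue", "TemporalSignature", function(x) x@lat)

#' @rdname accessors
#' @export
setGeneric("isValid", function(x) standardGeneric("isValid"))
#' @rdname accessors
#' @export
setMethod("isValid", "TemporalSignature", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("isValid", "ExpFit", function(x) x@valid)

#' @rdname accessors
#' @export
setMethod("$", "ParamSet", function(x, name) x@values[[name]])

#' @rdname accessors
#' @param ... parameter name/value pairs to replace.
#' @export
setGeneric("setParams", function(x, ...) standardGeneric("setParams"))
#' @rdname accessors
#' @export
setMethod("setParams", "ParamSet", function(x, ...) {
  upd <- list(...)
  bad <- setdiff(names(upd), names(x@values))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  x@values[names(upd)] <- upd
  x
})

#' @rdname accessors
#' @export
setGeneric("paramList", function(x) standardGeneric("paramList"))
#' @rdname accessors
#' @export
setMethod("paramList", "ParamSet", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("synapticWeights", function(x) standardGeneric("synapticWeights"))
#' @rdname accessors
#' @export
setMethod("synapticWeights", "SynapticMatrix", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("isExcitatory", function(x) standardGeneric("isExcitatory"))
#' @rdname accessors
#' @export
setMethod("isExcitatory", "SynapticMatrix", function(x) x@isExc)
#' @rdname accessors
#' @export
setMethod("isExcitatory", "SimResult", function(x) x@isExc)

#' @rdname accessors
#' @export
setGeneric("spikeRaster", function(x) standardGeneric("spikeRaster"))
#' @rdname accessors
#' @export
setMethod("spikeRaster", "SimResult", function(x) x@spikes)

#' @rdname accessors
#' @export
setGeneric("snapshotTimes", function(x) standardGeneric("snapshotTimes"))
#' @rdname accessors
#' @export
setMethod("snapshotTimes", "SimResult", function(x)
  as.numeric(names(x@snapshots)))

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setMethod("stateLabels", "StateSequence", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("statePeriods", function(x, raw = FALSE) standardGeneric("statePeriods"))
#' @rdname accessors
#' @param raw return periods before S0 reattribution.
#' @export
setMethod("statePeriods", "StateSequence", function(x, raw = FALSE)
  if (raw) x@rawPeriods else x@periods)

#' @rdname accessors
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))
#' @rdname accessors
#' @export
setMethod("densityValues", "SignatureDensity", function(x) x@density)

# -- show methods -------------------------------------------------------------

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s': %d spikes in [%.1f, %.1f) ms (%s, %s)\n",
              object@unitId, length(object@times), object@tStart,
              object@tStop, object@area, object@cellType))
})

setMethod("show", "PopulationRaster", function(object) {
  cat(sprintf("PopulationRaster: %d neurons x %d bins of %.3g ms (%.3g s total)\n",
              nrow(object@counts), ncol(object@counts), object@binWidth,
              ncol(object@counts) * object@binWidth / 1000))
})

setMethod("show", "IntervalSet", function(object) {
  cat(sprintf("IntervalSet: %d intervals (%s)\n", length(object@t0),
              paste(sprintf("%s: %d", unique(object@label),
                            tabulate(factor(object@label,
                                            unique(object@label)))),
                    collapse = ", ")))
})

setMethod("show", "ExpFit", function(object) {
  cat(sprintf("%s exponential fit: A=%.3g B=%.3g tau=%.1f ms rmse=%.3g (%s)\n",
              object@kind, object@A, object@B, object@tau, object@rmse,
              if (isTRUE(object@valid)) "valid" else "invalid"))
})

setMethod("show", "TemporalSignature", function(object) {
  if (object@valid)
    cat(sprintf("TemporalSignature '%s': LAT=%.1f ms, TAU=%.1f ms (n=%d spikes)\n",
                object@unitId, object@lat, object@tau, object@nSpikes))
  else
    cat(sprintf("TemporalSignature '%s': excluded (%s)\n",
                object@unitId, object@reason))
})

setMethod("show", "ParamSet", function(object) {
  cat(sprintf("%s with %d parameters\n", class(object), length(object@values)))
})

setMethod("show", "SynapticMatrix", function(object) {
  n <- nrow(object@weights)
  cat(sprintf("SynapticMatrix: %d neurons (%d Exc, %d Inh), %d connections\n",
              n, sum(object@isExc), sum(!object@isExc),
              sum(object@weights > 0)))
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: %d neurons, %.3g s, %d spikes, %d snapshots\n",
              object@nNeurons, object@duration / 1000, nrow(object@spikes),
              length(object@snapshots)))
})

setMethod("show", "HMMFit", function(object) {
  nN <- ncol(object@emission) -
    (if (identical(object@emissionType, "multinomial")) 1L else 0L)
  cat(sprintf("HMMFit (%s): %d states, %d neurons, logLik=%.2f (%s)\n",
              object@emissionType, nrow(object@transition), nN,
              object@logLik,
              if (object@converged) "converged" else "not converged"))
})

setMethod("show", "StateSequence", function(object) {
  cat(sprintf("StateSequence: %d bins of %.2g ms, %d periods (%d raw)\n",
              length(object@labels), object@binWidth, nrow(object@periods),
              nrow(object@rawPeriods)))
})

setMethod("show", "SignatureDensity", function(object) {
  cat(sprintf("SignatureDensity '%s': %d x %d grid, bw=(%.3g, %.3g)\n",
              object@tag, length(object@tauGrid), length(object@latGrid),
              object@bandwidth[1], object@bandwidth[2]))
})
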