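#' Read spike trains from delimited text
#'
#' Expects a delimited file with columns \code{unit_id} and \code{time_s}
#' (spike times in seconds). Times are converted to milliseconds internally;
#' all package constants (bins, time constants) are in ms. An optional
#' metadata file with columns \code{unit_id}, \code{area}, \code{cell_type},
#' \code{ap_mm} is joined by unit.
#'
#' @param path path to the spike file.
#' @param metaPath optional path to the metadata file.
#' @param sep field separator (default: any whitespace via
#'   \code{read.table}; pass "," for CSV).
#' @return A list of \linkS4class{SpikeTrain}, one per unit.
#' @export
readSpikeTrains <- function(path, metaPath = NULL, sep = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("unit_id", "time_s") %in% names(df)))
    stop("expected columns unit_id, time_s")
  if (nrow(df) == 0) return(list())
  meta <- NULL
  if (!is.null(metaPath)) {
    meta <- utils::read.table(metaPath, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
  }
  out <- lapply(split(df$time_s, df$unit_id), identity)
  trains <- vector("list", length(out))
  names(trains) <- names(out)
  for (u in names(out)) {
    ts <- out[[u]] * 1000  # s -> ms
    if (any(diff(ts) <= 0))
      stop("unsorted or duplicate timestamps for unit '", u, "'")
    area <- "other"; cellType <- "unknown"; ap <- NA_real_
    if (!is.null(meta)) {
      row <- meta[meta$unit_id == u, , drop = FALSE]
      if (nrow(row) == 1) {
        if ("area" %in% names(row) && row$area %in% c("MCC", "LPFC"))
          area <- row$area
        if ("cell_type" %in% names(row)) {
          if (row$cell_type %in% c("FS", "RS")) cellType <- row$cell_type
          else warning("unknown cell_type '", row$cell_type, "' for unit '",
                       u, "'; set to unknown")
        }
        if ("ap_mm" %in% names(row)) ap <- as.numeric(row$ap_mm)
      }
    }
    trains[[u]] <- SpikeTrain(ts, tStart = 0, tStop = max(ts), unitId = u,
                              area = area, cellType = cellType,
                              apPosition = ap)
  }
  trains
}

#' Write spike trains to delimited text
#'
#' Inverse of \code{\link{readSpikeTrains}}: one row per spike, columns
#' \code{unit_id} and \code{time_s}. Times are written in seconds with enough
#' digits that a round trip preserves them to well under a microsecond.
#'
#' @param trains list of \linkS4class{SpikeTrain}.
#' @param path output path.
#' @export
writeSpikeTrains <- function(trains, path) {
  df <- do.call(rbind, lapply(trains, function(tr)
    data.frame(unit_id = unitId(tr), time_s = spikeTimes(tr) / 1000)))
  if (is.null(df)) df <- data.frame(unit_id = character(), time_s = numeric())
  utils::write.table(format(df, digits = 12, scientific = FALSE), path,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bin spike trains into a population raster
#'
#' Half-open bins \code{[t, t + binWidth)}; a spike exactly on an edge goes to
#' the later bin. Total counts within the window are conserved for any bin
#' width.
#'
#' @param trains list of \linkS4class{SpikeTrain} sharing a clock.
#' @param binWidth bin width (ms); 0.5 ms is the resolution used for HMM
#'   segmentation.
#' @param window numeric c(t0, t1): half-open analysis window (ms). Defaults
#'   to the union of the trains' bounds.
#' @return A \linkS4class{PopulationRaster}.
#' @export
binRaster <- function(trains, binWidth = 0.5, window = NULL) {
  stopifnot(binWidth > 0, length(trains) > 0)
  if (is.null(window)) {
    window <- c(min(vapply(trains, function(x) recordingBounds(x)[1], 0)),
                max(vapply(trains, function(x) recordingBounds(x)[2], 0)))
  }
  nBins <- ceiling((window[2] - window[1]) / binWidth)
  counts <- matrix(0L, nrow = length(trains), ncol = nBins)
  for (i in seq_along(trains)) {
    b <- recordingBounds(trains[[i]])
    if (b[2] <= window[1] || b[1] >= window[2])
      warning("window outside bounds of train ", i, "; zero-filled")
    ts <- spikeTimes(trains[[i]])
    ts <- ts[ts >= window[1] & ts < window[1] + nBins * binWidth]
    if (length(ts)) {
      idx <- floor((ts - window[1]) / binWidth) + 1
      tab <- tabulate(idx, nbins = nBins)
      counts[i, ] <- as.integer(tab)
    }
  }
  meta <- data.frame(
    area = vapply(trains, function(x) x@area, ""),
    cellType = vapply(trains, function(x) x@cellType, ""))
  new("PopulationRaster", counts = counts, binWidth = binWidth,
      tStart = window[1], neuronMeta = meta)
}

#' Assemble a pseudo-population raster
#'
#' Pools units recorded in different sessions onto a common clock: each unit's
#' spikes are taken from its own recording start, truncated to a common
#' duration, and binned at 0.5 ms. Cross-session phase information is
#' deliberately not aligned, so decoded population states are chimeric
#' combinations of per-session dynamics; this still captures the temporal
#' structure of collective activity when simultaneous samples are too small.
#'
#' @param trains list of \linkS4class{SpikeTrain}.
#' @param duration common duration (ms); default 600 s.
#' @param binWidth bin width (ms).
#' @return A \linkS4class{PopulationRaster}. Trains shorter than
#'   \code{duration} are excluded with a warning.
#' @export
buildPseudoPopulation <- function(trains, duration = 6e5, binWidth = 0.5) {
  keep <- vapply(trains, function(tr) {
    b <- recordingBounds(tr)
    b[2] - b[1] >= duration
  }, TRUE)
  if (any(!keep))
    warning(sum(!keep), " train(s) shorter than ", duration,
            " ms excluded from pseudo-population")
  trains <- trains[keep]
  if (!length(trains)) stop("no train covers the requested duration")
  shifted <- lapply(trains, function(tr) {
    t0 <- recordingBounds(tr)[1]
    ts <- spikeTimes(tr) - t0
    ts <- ts[ts >= 0 & ts < duration]
    SpikeTrain(ts, tStart = 0, tStop = duration, unitId = unitId(tr),
               area = tr@area, cellType = tr@cellType)
  })
  binRaster(shifted, binWidth = binWidth, window = c(0, duration))
}

#' Segment a session into engage and pause intervals
#'
#' Pauses are periods of at least \code{minPause} (default 60 s) without trial
#' initialization: a gap between the end of one trial and the start of the
#' next that reaches the threshold is labelled \code{pause}, the remainder of
#' the session \code{engage}. The start of the first pause is recorded for
#' the time-on-task control.
#'
#' @param events a \linkS4class{TrialEvents}.
#' @param minPause minimum pause duration (ms).
#' @return An \linkS4class{IntervalSet} tiling the session.
#' @export
segmentEngagePause <- function(events, minPause = 6e4) {
  tr <- trialTable(events)
  if (nrow(tr) < 1) stop("need at least one trial")
  starts <- tr$trialStart
  ends <- tr$trialEnd
  sessionStart <- starts[1]
  sessionEnd <- ends[nrow(tr)]
  if (nrow(tr) == 1)
    return(IntervalSet(sessionStart, sessionEnd, "engage"))
  gapT0 <- ends[-nrow(tr)]
  gapT1 <- starts[-1]
  isPause <- (gapT1 - gapT0) >= minPause
  t0 <- numeric(); t1 <- numeric(); lab <- character()
  cursor <- sessionStart
  for (i in seq_along(gapT0)) {
    if (isPause[i]) {
      if (gapT0[i] > cursor) {
        t0 <- c(t0, cursor); t1 <- c(t1, gapT0[i]); lab <- c(lab, "engage")
      }
      t0 <- c(t0, gapT0[i]); t1 <- c(t1, gapT1[i]); lab <- c(lab, "pause")
      cursor <- gapT1[i]
    }
  }
  if (sessionEnd > cursor) {
    t0 <- c(t0, cursor); t1 <- c(t1, sessionEnd); lab <- c(lab, "engage")
  }
  fp <- if (any(lab == "pause")) t0[lab == "pause"][1] else NA_real_
  IntervalSet(t0, t1, lab, firstPauseStart = fp)
}

#' Restrict a spike train to a set of intervals
#'
#' Spikes outside the intervals are removed and the train carries the interval
#' structure, so that downstream lagged differences are computed within single
#' intervals only (pairs spanning a gap are excluded rather than splicing
#' segments together, which would fabricate short lags).
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param intervals an \linkS4class{IntervalSet}; an optional \code{label}
#'   restricts to intervals with that label.
#' @param label optional label filter ("engage" or "pause").
#' @return A \linkS4class{SpikeTrain} (possibly empty).
#' @export
restrictTrain <- function(train, intervals, label = NULL) {
  tab <- intervalTable(intervals)
  if (!is.null(label)) tab <- tab[tab$label == label, , drop = FALSE]
  if (!nrow(tab)) return(SpikeTrain(numeric(0), 0, 0, unitId = unitId(train),
                                    area = train@area, cellType = train@cellType))
  ts <- spikeTimes(train)
  keep <- rep(FALSE, length(ts))
  for (i in seq_len(nrow(tab)))
    keep <- keep | (ts >= tab$t0[i] & ts < tab$t1[i])
  SpikeTrain(ts[keep], tStart = min(tab$t0), tStop = max(tab$t1),
             unitId = unitId(train), area = train@area,
             cellType = train@cellType, apPosition = train@apPosition,
             intervals = cbind(t0 = tab$t0, t1 = tab$t1))
}
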