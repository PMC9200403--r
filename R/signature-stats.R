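#' Rank-based inverse normal (BLOM) transform
#'
#' Y_i = qnorm((r_i - c) / (N - 2c + 1)) with c = 3/8, where r_i is the rank
#' of x_i among the N observations. Ties receive average ranks. The transform
#' is monotone in ranks and therefore invariant to any strictly increasing
#' re-expression of the input; the output is approximately standard normal
#' for continuous inputs, so regular parametric analyses can be run on it.
#'
#' @param x numeric vector, finite, length >= 2.
#' @param c the Blom constant (default 3/8).
#' @return list with components \code{values} (transformed scores),
#'   \code{ranks}, \code{c} and \code{N}.
#' @export
blomTransform <- function(x, c = 3 / 8) {
  if (length(x) < 2) stop("need N >= 2")
  if (any(!is.finite(x))) stop("non-finite values")
  if (length(unique(x)) == 1) {
    warning("all values equal; returning zero scores")
    return(list(values = rep(0, length(x)), ranks = rank(x), c = c,
                N = length(x)))
  }
  r <- rank(x, ties.method = "average")
  N <- length(x)
  list(values = stats::qnorm((r - c) / (N - 2 * c + 1)), ranks = r, c = c,
       N = N)
}

#' Context modulation index for a timescale pair
#'
#' log(TAU_a) / log(TAU_b) with natural logarithms; 1 means no modulation.
#' Which condition is the numerator is the caller's explicit choice (e.g.
#' slow/fast block speed, or empty/full gauge).
#'
#' @param tauA,tauB timescales (ms), both > 1 ms for log positivity.
#' @return The index, or NA when either timescale is <= 1 ms.
#' @export
modulationIndex <- function(tauA, tauB) {
  out <- ifelse(tauA > 1 & tauB > 1 & is.finite(tauA) & is.finite(tauB),
                log(tauA) / log(tauB), NA_real_)
  out
}

#' Median split of units by a timescale metric
#'
#' Within each stratum (area x cell type), units with a metric value below
#' the stratum median are labelled "short" and above it "long"; values
#' exactly at the median go to "short" (deterministic rule). Strata with
#' fewer than \code{minUnits} units are skipped.
#'
#' @param values numeric metric (e.g. TAU) per unit.
#' @param strata optional factor of stratum labels (one per unit); a single
#'   stratum when omitted.
#' @param minUnits minimum stratum size (default 4).
#' @return character vector of labels ("short"/"long", NA for skipped
#'   strata), with the per-stratum medians as the "medians" attribute.
#' @export
medianSplit <- function(values, strata = NULL, minUnits = 4) {
  if (is.null(strata)) strata <- rep("all", length(values))
  strata <- as.character(strata)
  labels <- rep(NA_character_, length(values))
  meds <- c()
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < minUnits) {
      warning("stratum '", s, "' has fewer than ", minUnits,
              " units; skipped")
      next
    }
    m <- stats::median(values[idx])
    meds[s] <- m
    labels[idx] <- ifelse(values[idx] <= m, "short", "long")
  }
  attr(labels, "medians") <- meds
  labels
}

#' Permute median-split group allocation
#'
#' Re-draws short/long labels at random while preserving the group sizes
#' within each stratum, for building permutation null distributions of
#' group-difference statistics.
#'
#' @param labels labels as returned by \code{\link{medianSplit}}.
#' @param strata the stratum factor used for the split (or NULL).
#' @return permuted labels.
#' @export
permuteSplit <- function(labels, strata = NULL) {
  if (is.null(strata)) strata <- rep("all", length(labels))
  strata <- as.character(strata)
  out <- labels
  for (s in unique(strata)) {
    idx <- which(strata == s & !is.na(labels))
    out[idx] <- sample(labels[idx])
  }
  attributes(out) <- attributes(labels)
  out
}
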