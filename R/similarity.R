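#' Bivariate kernel density of (TAU, LAT) signatures
#'
#' Normal-kernel KDE on a fixed shared grid (TAU in [0, 1000] ms, LAT in
#' [0, 300] ms by default), with Scott's-rule bandwidths per dimension
#' (sd * n^(-1/6)), normalized to integrate to 1 over the grid so that
#' densities of different populations are directly comparable.
#'
#' @param tau,lat coordinates of the points (ms); at least 10 points.
#' @param tauLim,latLim grid limits (ms).
#' @param n grid resolution per dimension.
#' @param bandwidth optional c(tau, lat) bandwidth override (kernel sd).
#' @param tag population label.
#' @return A \linkS4class{SignatureDensity}.
#' @export
bivariateDensity <- function(tau, lat, tauLim = c(0, 1000),
                             latLim = c(0, 300), n = 200,
                             bandwidth = NULL, tag = "") {
  ok <- is.finite(tau) & is.finite(lat)
  tau <- tau[ok]; lat <- lat[ok]
  if (length(tau) < 10) stop("need at least 10 points")
  if (stats::sd(tau) == 0 || stats::sd(lat) == 0)
    stop("degenerate (zero-variance) point cloud")
  if (is.null(bandwidth)) {
    nn <- length(tau)
    bandwidth <- c(stats::sd(tau), stats::sd(lat)) * nn^(-1 / 6)
  }
  # MASS::kde2d's h is 4 x the kernel sd
  kd <- MASS::kde2d(tau, lat, h = 4 * bandwidth, n = n,
                    lims = c(tauLim, latLim))
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  z <- kd$z / (sum(kd$z) * dx * dy)
  new("SignatureDensity", tauGrid = kd$x, latGrid = kd$y, density = z,
      bandwidth = bandwidth, tag = tag)
}

#' Similarity of a cellular-model point to a data density
#'
#' The similarity of one model parameterization to a cortical population is
#' the probability density of that population at the (TAU, LAT) the model
#' produces (bilinear interpolation on the KDE grid). Models whose mean
#' firing rate exceeds 20 Hz discharge unrealistically and are discarded
#' (NA with a discarded flag).
#'
#' @param density a \linkS4class{SignatureDensity} of the data population.
#' @param tau,lat the model's signature (ms).
#' @param rate the model's mean firing rate (Hz).
#' @param maxRate realism bound (Hz).
#' @return list(similarity, discarded).
#' @export
cellularSimilarity <- function(density, tau, lat, rate = 0, maxRate = 20) {
  if (rate > maxRate)
    return(list(similarity = NA_real_, discarded = TRUE))
  gx <- density@tauGrid; gy <- density@latGrid
  if (tau < min(gx) || tau > max(gx) || lat < min(gy) || lat > max(gy)) {
    warning("model point off the density grid; similarity 0")
    return(list(similarity = 0, discarded = FALSE))
  }
  ix <- findInterval(tau, gx, all.inside = TRUE)
  iy <- findInterval(lat, gy, all.inside = TRUE)
  fx <- (tau - gx[ix]) / (gx[ix + 1] - gx[ix])
  fy <- (lat - gy[iy]) / (gy[iy + 1] - gy[iy])
  z <- density@density
  val <- (1 - fx) * (1 - fy) * z[ix, iy] + fx * (1 - fy) * z[ix + 1, iy] +
    (1 - fx) * fy * z[ix, iy + 1] + fx * fy * z[ix + 1, iy + 1]
  list(similarity = unname(val), discarded = FALSE)
}

#' Normalized Frobenius similarity of two signature densities
#'
#' S(U, N) = <U, N>_F / (||U||_F ||N||_F) on a shared grid; bounded in
#' [0, 1] for non-negative densities (Cauchy-Schwarz), symmetric, and
#' invariant to positive rescaling of either density.
#'
#' @param U,N \linkS4class{SignatureDensity} objects on the same grid.
#' @return The similarity in [0, 1].
#' @export
networkSimilarity <- function(U, N) {
  if (!isTRUE(all.equal(U@tauGrid, N@tauGrid)) ||
      !isTRUE(all.equal(U@latGrid, N@latGrid)))
    stop("densities are on different grids")
  u <- U@density; v <- N@density
  den <- sqrt(sum(u * u)) * sqrt(sum(v * v))
  if (den == 0) return(0)
  sum(u * v) / den
}

#' Overall similarity combining RS/Exc and FS/Inh populations
#'
#' S = pExc * S(RS, Exc) + (1 - pExc) * S(FS, Inh), with pExc = 0.8
#' reflecting the cortical excitatory fraction.
#'
#' @param sRsExc similarity of the RS data density to the excitatory model
#'   density.
#' @param sFsInh similarity of the FS data density to the inhibitory model
#'   density.
#' @param pExc excitatory weight.
#' @export
overallSimilarity <- function(sRsExc, sFsInh, pExc = 0.8) {
  pExc * sRsExc + (1 - pExc) * sFsInh
}

#' Best-fit parameters from a similarity map
#'
#' Given a similarity value per grid cell, finds the region above 80% of
#' the maximum and returns its similarity-weighted centroid, the rule used
#' to read best-fit conductance couples off two-dimensional sweeps.
#'
#' @param map data.frame with two parameter columns and a
#'   \code{similarity} column.
#' @param level contour level as a fraction of the maximum.
#' @return named numeric: weighted mean of each parameter over the
#'   above-level region.
#' @export
similarityCentroid <- function(map, level = 0.8) {
  s <- map$similarity
  keep <- which(s >= level * max(s, na.rm = TRUE))
  pars <- setdiff(names(map), "similarity")
  vapply(pars, function(p)
    stats::weighted.mean(map[[p]][keep], s[keep]), numeric(1))
}
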