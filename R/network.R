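#' Standard parameters of the recurrent network model
#'
#' 605-neuron conductance-based leaky integrate-and-fire network, 80%
#' excitatory / 20% inhibitory, with CAN and AHP intrinsic currents in
#' excitatory neurons, AMPA/NMDA/GABA-A/GABA-B recurrent synapses (second
#' order kinetics for the slow receptors), a constant AMPA feed-forward
#' drive, spike-increment calcium dynamics and a uniform 0.5-ms synaptic
#' delay. Presets set the (gAHP, gGABAB) couple:
#' \itemize{
#'   \item \code{LPFCm}: gAHP = 0.022, gGABAB = 0.0035 mS/cm2
#'   \item \code{MCCm}: gAHP = 0.087, gGABAB = 0.0143 mS/cm2
#'   \item \code{MCCm_LPFC_AHP}: MCCm with the LPFCm gAHP
#'   \item \code{MCCm_LPFC_GABAB}: MCCm with the LPFCm gGABAB
#' }
#' All presets use gCAN = 0.025 mS/cm2. The integrate-and-fire resting/reset
#' potential (-65 mV) is also the leak reversal.
#'
#' @param preset one of the preset names above, or NULL for the standard
#'   base set (LPFCm conductances).
#' @param ... parameter overrides by name.
#' @return A \linkS4class{NetworkParams}.
#' @export
networkParams <- function(preset = c("LPFCm", "MCCm", "MCCm_LPFC_AHP",
                                     "MCCm_LPFC_GABAB"), ...) {
  preset <- match.arg(preset)
  g <- switch(preset,
    LPFCm = c(gAHP = 0.022, gGABAB = 0.0035),
    MCCm = c(gAHP = 0.087, gGABAB = 0.0143),
    MCCm_LPFC_AHP = c(gAHP = 0.022, gGABAB = 0.0143),
    MCCm_LPFC_GABAB = c(gAHP = 0.087, gGABAB = 0.0035))
  v <- list(
    N = 605, pExc = 0.8, nExc = 484, nInh = 121,
    pEE = 0.3, pEI = 0.3, pII = 0.3, pIE = 0.55,
    muW = 0.03, sigmaW = 0.02, reciprocalFactor = 4,
    C = 1, gL = 0.05, VL = -65, Vrest = -65, theta = -50,
    refractory = 3, deltaCa = 0.2, Ca0 = 0.1, tauCa = 25,
    gCAN = 0.025, VCAN = 30, alphaCAN = 0.0015, betaCAN = 0.005,
    gAHP = unname(g["gAHP"]), VAHP = -90, alphaAHP = 0.025,
    betaAHP = 0.025,
    gAMPA = 0.23, gAMPAFF = 0.23, pAMPAFF = 0.101, tauAMPA = 2.5,
    gNMDA = 0.35, alphaNMDA = 0.275, tauNMDArise = 4.65,
    tauNMDAdecay = 75,
    gGABAA = 0.4, tauGABAA = 10,
    gGABAB = unname(g["gGABAB"]), alphaGABAB = 0.015, tauGABABrise = 90,
    tauGABABdecay = 160,
    VAMPA = 0, VNMDA = 0, VGABAA = -70, VGABAB = -90, Mg = 1.5,
    Vmean = -57.5, deltaX = 0.1, deltaTsyn = 0.5, dt = 0.5)
  p <- new("NetworkParams", values = v)
  if (...length()) p <- setParams(p, ...)
  p
}

# moment-matched log-normal parameters: muW/sigmaW are the mean and sd of the
# variate itself unless asLog = TRUE
.lognormalPars <- function(muW, sigmaW, asLog = FALSE) {
  if (asLog) return(c(meanlog = muW, sdlog = sigmaW))
  s2 <- log(1 + (sigmaW / muW)^2)
  c(meanlog = log(muW) - s2 / 2, sdlog = sqrt(s2))
}

#' Draw the synaptic matrix of a network instance
#'
#' Block-wise sparse Bernoulli connectivity with no autapses. Unordered E-E
#' pairs are drawn as none / unidirectional / bidirectional with the
#' bidirectional probability set to \code{reciprocalFactor} times the
#' independent-Bernoulli expectation pEE^2 while the marginal connection
#' probability stays pEE; the factor is capped at 1/pEE (full reciprocity)
#' when the requested over-representation is infeasible at the given
#' density. Weights are i.i.d. log-normal with mean \code{muW} and sd
#' \code{sigmaW} (of the variate; moment-matched). Per-postsynaptic GABA-A
#' and GABA-B maximal conductances are solved from the recurrent balance
#' equations using each neuron's excitatory/inhibitory weight-sum ratio at
#' Vmean = (Vrest + theta)/2.
#'
#' @param p a \linkS4class{NetworkParams}.
#' @param seed integer seed.
#' @param weightsAsLog treat muW/sigmaW as log-scale parameters.
#' @return A \linkS4class{SynapticMatrix}.
#' @export
buildNetwork <- function(p, seed = 1, weightsAsLog = FALSE) {
  withSeed(seed, {
    N <- p$N; nE <- p$nExc; nI <- p$nInh
    stopifnot(nE + nI == N)
    isExc <- c(rep(TRUE, nE), rep(FALSE, nI))
    adj <- matrix(FALSE, N, N)  # adj[i, j]: i -> j exists

    # E-E: unordered pairs with over-represented reciprocity
    pEE <- p$pEE
    rho <- min(p$reciprocalFactor, 1 / pEE)
    b <- rho * pEE^2          # P(bidirectional)
    u <- pEE - b              # P(each unidirectional direction)
    if (u < 0) stop("infeasible reciprocal motif parameters")
    pairIdx <- which(upper.tri(matrix(0, nE, nE)), arr.ind = TRUE)
    r <- stats::runif(nrow(pairIdx))
    bi <- r < b
    uni1 <- r >= b & r < b + u          # i -> j only
    uni2 <- r >= b + u & r < b + 2 * u  # j -> i only
    ii <- pairIdx[, 1]; jj <- pairIdx[, 2]
    adj[cbind(ii[bi | uni1], jj[bi | uni1])] <- TRUE
    adj[cbind(jj[bi | uni2], ii[bi | uni2])] <- TRUE

    # other blocks: independent Bernoulli
    eIdx <- which(isExc); iIdx <- which(!isExc)
    adj[eIdx, iIdx] <- matrix(stats::runif(nE * nI) < p$pEI, nE, nI)
    adj[iIdx, eIdx] <- matrix(stats::runif(nI * nE) < p$pIE, nI, nE)
    blockII <- matrix(stats::runif(nI * nI) < p$pII, nI, nI)
    diag(blockII) <- FALSE
    adj[iIdx, iIdx] <- blockII
    diag(adj) <- FALSE

    # ensure every neuron receives inhibition (balance defined); redraw rows
    for (j in seq_len(N)) {
      tries <- 0
      while (!any(adj[iIdx[iIdx != j], j]) && tries < 100) {
        pin <- if (isExc[j]) p$pIE else p$pII
        pre <- iIdx[iIdx != j]
        adj[pre, j] <- stats::runif(length(pre)) < pin
        tries <- tries + 1
      }
      if (!any(adj[iIdx[iIdx != j], j]))
        adj[sample(iIdx[iIdx != j], 1), j] <- TRUE
    }

    lp <- .lognormalPars(p$muW, p$sigmaW, weightsAsLog)
    W <- matrix(0, N, N)
    ne <- sum(adj)
    W[adj] <- stats::rlnorm(ne, lp["meanlog"], lp["sdlog"])

    sumE <- colSums(W[eIdx, , drop = FALSE])
    sumI <- colSums(W[iIdx, , drop = FALSE])
    drive <- -(p$Vmean - p$VAMPA)
    gGA <- p$gGABAA * drive / (p$Vmean - p$VGABAA) * sumE / sumI
    gGB <- p$gGABAB * drive / (p$Vmean - p$VGABAB) * sumE / sumI
    new("SynapticMatrix", weights = W, isExc = isExc, gGABAA = gGA,
        gGABAB = gGB, seed = as.numeric(seed))
  })
}

# canonical name for a snapshot taken at time t (ms)
.snapKey <- function(t) sprintf("%.10g", t)

# fresh random initial state for a network simulation
.netInitState <- function(p, seed) {
  withSeed(seed, {
    N <- p$N
    ca0 <- p$Ca0
    list(V = stats::runif(N, p$Vrest, p$theta),
         ref = integer(N), Ca = rep(ca0, N),
         pCAN = rep(p$alphaCAN * ca0 / (p$alphaCAN * ca0 + p$betaCAN), N),
         pAHP = rep(p$alphaAHP * ca0 / (p$alphaAHP * ca0 + p$betaAHP), N),
         pA = numeric(N), qN = numeric(N), pN = numeric(N),
         pGA = numeric(N), qB = numeric(N), pB = numeric(N),
         pending = integer(0))
  })
}

.netParList <- function(p) {
  list(C = p$C, gL = p$gL, VL = p$VL, theta = p$theta, Vrest = p$Vrest,
       refSteps = as.integer(round(p$refractory / p$dt)),
       gCAN = p$gCAN, VCAN = p$VCAN, alphaCAN = p$alphaCAN,
       betaCAN = p$betaCAN, gAHP = p$gAHP, VAHP = p$VAHP,
       alphaAHP = p$alphaAHP, betaAHP = p$betaAHP,
       Ca0 = p$Ca0, tauCa = p$tauCa, deltaCa = p$deltaCa,
       gAMPA = p$gAMPA, gNMDA = p$gNMDA,
       VAMPA = p$VAMPA, VNMDA = p$VNMDA, VGABAA = p$VGABAA,
       VGABAB = p$VGABAB,
       tauAMPA = p$tauAMPA, tauGABAA = p$tauGABAA,
       tauNMDArise = p$tauNMDArise, tauNMDAdecay = p$tauNMDAdecay,
       alphaNMDA = p$alphaNMDA,
       tauGABABrise = p$tauGABABrise, tauGABABdecay = p$tauGABABdecay,
       alphaGABAB = p$alphaGABAB,
       deltaX = p$deltaX, Mg = p$Mg,
       gAMPAFF = p$gAMPAFF, pAMPAFF = p$pAMPAFF)
}

#' Simulate the recurrent network
#'
#' Forward-Euler integration at dt = 0.5 ms. Threshold crossings reset the
#' membrane to Vrest with a 3-ms refractory period; spike effects are
#' delivered after the uniform 0.5-ms synaptic delay. The model is
#' deterministic given the synaptic matrix and initial state (activity is
#' chaotic, not noise-driven); the seed only draws the initial condition.
#' Snapshots store the full dynamical state, so a resumed simulation
#' reproduces the original trajectory exactly.
#'
#' @param p a \linkS4class{NetworkParams}.
#' @param syn a \linkS4class{SynapticMatrix} from \code{\link{buildNetwork}}.
#' @param duration simulated time (ms).
#' @param seed seed for the initial condition (ignored when \code{init}
#'   given).
#' @param snapshotTimes times (ms) at which to store full state snapshots.
#' @param init optional initial state (a snapshot) to resume from.
#' @return A \linkS4class{SimResult}.
#' @export
simulateNetwork <- function(p, syn, duration = 6e5, seed = 1,
                            snapshotTimes = numeric(0), init = NULL) {
  dt <- p$dt
  nSteps <- as.integer(round(duration / dt))
  if (is.null(init)) init <- .netInitState(p, seed)
  snapSteps <- as.integer(round(snapshotTimes / dt))
  Wt <- t(syn@weights)  # post-major: column i = outgoing weights of i
  res <- .net_simulate(Wt, syn@isExc, syn@gGABAA, syn@gGABAB,
                       .netParList(p), nSteps, dt, init, snapSteps, TRUE)
  spikes <- data.frame(neuron = res$spikeNeuron,
                       time = res$spikeStep * dt)
  snaps <- res$snapshots
  if (length(snaps))
    names(snaps) <- vapply(snaps, function(s) .snapKey(s$step * dt), "")
  snaps[["final"]] <- res$finalState
  new("SimResult", spikes = spikes, nNeurons = p$N, isExc = syn@isExc,
      duration = duration, dt = dt, snapshots = snaps,
      seed = as.numeric(seed))
}

#' Convert a SimResult to per-neuron spike trains
#'
#' @param sim a \linkS4class{SimResult}.
#' @param neurons neuron indices (default all).
#' @return list of \linkS4class{SpikeTrain}.
#' @export
simToTrains <- function(sim, neurons = seq_len(sim@nNeurons)) {
  sp <- split(sim@spikes$time, factor(sim@spikes$neuron,
                                      levels = seq_len(sim@nNeurons)))
  lapply(neurons, function(j) {
    SpikeTrain(sp[[j]], tStart = 0, tStop = sim@duration,
               unitId = sprintf("n%03d", j),
               cellType = if (sim@isExc[j]) "RS" else "FS")
  })
}

#' Per-neuron spiking statistics
#'
#' Rate, ISI coefficient of variation (CV), CV2, Lv and the Fano factor of
#' counts in fixed windows, per neuron and averaged over neurons with at
#' least \code{minSpikes} spikes.
#'
#' @param sim a \linkS4class{SimResult}.
#' @param minSpikes inclusion threshold.
#' @param fanoWindow window for Fano-factor counts (ms).
#' @return data.frame with one row per included neuron and a "means"
#'   attribute.
#' @export
spikingStatistics <- function(sim, minSpikes = 100, fanoWindow = 100) {
  sp <- split(sim@spikes$time, factor(sim@spikes$neuron,
                                      levels = seq_len(sim@nNeurons)))
  rows <- lapply(seq_len(sim@nNeurons), function(j) {
    ts <- sp[[j]]
    if (length(ts) < minSpikes) return(NULL)
    isi <- diff(ts)
    cv <- stats::sd(isi) / mean(isi)
    a <- isi[-length(isi)]; b <- isi[-1]
    cv2 <- mean(2 * abs(b - a) / (a + b))
    lv <- mean(3 * (a - b)^2 / (a + b)^2)
    nb <- floor(sim@duration / fanoWindow)
    cnt <- tabulate(pmin(floor(ts / fanoWindow) + 1, nb), nbins = nb)
    fano <- stats::var(cnt) / mean(cnt)
    data.frame(neuron = j, isExc = sim@isExc[j],
               rate_hz = 1000 * length(ts) / sim@duration,
               cv = cv, cv2 = cv2, lv = lv, fano = fano)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  else attr(out, "means") <- colMeans(out[, c("rate_hz", "cv", "cv2", "lv",
                                              "fano")])
  out
}

#' Population temporal signatures of a network simulation
#'
#' Extracts the (LAT, TAU) signature of every neuron and summarizes by
#' population (Exc/Inh).
#'
#' @param sim a \linkS4class{SimResult}.
#' @param minSpikes minimum spikes per neuron for a fit.
#' @param seed seed for fit restarts.
#' @param nRestarts fit restarts per neuron.
#' @return data.frame (neuron, isExc, LAT_ms, TAU_ms, rate_hz, valid) with a
#'   "summary" attribute of population means.
#' @export
networkSignatures <- function(sim, minSpikes = 1000, seed = 1,
                              nRestarts = 20) {
  trains <- simToTrains(sim)
  rows <- lapply(seq_along(trains), function(j) {
    sig <- extractSignature(trains[[j]], minSpikes = minSpikes, seed = seed,
                            nRestarts = nRestarts)
    data.frame(neuron = j, isExc = sim@isExc[j], LAT_ms = latValue(sig),
               TAU_ms = tauValue(sig),
               rate_hz = 1000 * length(spikeTimes(trains[[j]])) /
                 sim@duration,
               valid = isValid(sig))
  })
  out <- do.call(rbind, rows)
  ok <- out$valid
  summ <- data.frame(
    population = c("Exc", "Inh"),
    LAT_ms = c(mean(out$LAT_ms[ok & out$isExc]),
               mean(out$LAT_ms[ok & !out$isExc])),
    TAU_ms = c(mean(out$TAU_ms[ok & out$isExc]),
               mean(out$TAU_ms[ok & !out$isExc])),
    nValid = c(sum(ok & out$isExc), sum(ok & !out$isExc)),
    n = c(sum(out$isExc), sum(!out$isExc)))
  attr(out, "summary") <- summ
  out
}

#' Two-dimensional parameter sweep of the network model
#'
#' For each cell of a (gAHP, gGABAB) grid (or any other parameter couple),
#' builds and simulates \code{reps} networks, extracts population LAT and
#' TAU for excitatory and inhibitory neurons, and averages. Cells in which
#' more than half the neurons fail signature extraction are flagged.
#'
#' @param grid data.frame of parameter values, one row per grid cell;
#'   column names must be \linkS4class{NetworkParams} names.
#' @param p base parameter set.
#' @param reps simulations per cell.
#' @param duration per-simulation time (ms).
#' @param seed base seed.
#' @param minSpikes per-neuron fit threshold.
#' @return data.frame: grid columns plus LAT_exc, TAU_exc, LAT_inh, TAU_inh,
#'   rate_hz, fracValid, flagged.
#' @export
sweepNetwork <- function(grid, p = networkParams("LPFCm"), reps = 5,
                         duration = 6e5, seed = 1, minSpikes = 1000) {
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    pg <- do.call(setParams, c(list(p), as.list(grid[g, , drop = FALSE])))
    acc <- NULL
    for (r in seq_len(reps)) {
      s <- seed + (g - 1) * reps + (r - 1)
      syn <- buildNetwork(pg, seed = s)
      sim <- simulateNetwork(pg, syn, duration = duration, seed = s + 1e4)
      sigs <- networkSignatures(sim, minSpikes = minSpikes, seed = s)
      summ <- attr(sigs, "summary")
      acc <- rbind(acc, data.frame(
        LAT_exc = summ$LAT_ms[1], TAU_exc = summ$TAU_ms[1],
        LAT_inh = summ$LAT_ms[2], TAU_inh = summ$TAU_ms[2],
        rate_hz = mean(sigs$rate_hz), fracValid = mean(sigs$valid)))
    }
    m <- colMeans(acc, na.rm = TRUE)
    rows[[g]] <- cbind(grid[g, , drop = FALSE], as.data.frame(t(m)),
                       data.frame(flagged = m["fracValid"] < 0.5))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
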