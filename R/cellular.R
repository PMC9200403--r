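#' Standard parameters of the conductance-based pyramidal-cell model
#'
#' Hodgkin-Huxley-type single-compartment model of a frontal pyramidal neuron
#' with leak, spike (Na/K), high-threshold calcium (CaL), calcium-activated
#' non-specific cationic (CAN), medium after-hyperpolarization potassium
#' (AHP), low-threshold calcium (CaT) and hyperpolarization-activated (H)
#' currents, plus sub-membrane shell calcium dynamics. Units: mV, ms,
#' mS/cm2, uF/cm2, uM, cm.
#'
#' CaT and H conductances default to zero; their gating uses standard
#' Boltzmann forms. The CaL activation time constant follows
#' tau(V) = 10 / (alphaCaL + betaCaL V) (guarded to stay positive and
#' above 0.1 ms); the defaults make CaL activation fast (1-2 ms) at spike
#' voltages and effectively frozen far below threshold, so calcium entry is
#' spike-gated. Set \code{betaCaL} = 0 for a constant time constant.
#'
#' @param ... parameter overrides by name.
#' @return A \linkS4class{CellularParams}.
#' @export
cellularParams <- function(...) {
  v <- list(
    C = 1, gL = 0.05, VL = -70,
    gNa = 30, VNa = 50, gK = 2, VK = -90,
    gCaL = 0.01, VCaL = 150, VhalfCaL = -20, kCaL = 6,
    alphaCaL = 6, betaCaL = 0.1,
    gCAN = 0.05, VCAN = 30, alphaCAN = 0.0015, betaCAN = 0.005,
    gAHP = 0.1, VAHP = -90, alphaAHP = 0.025, betaAHP = 0.025,
    gCaT = 0, VCaT = 120, gH = 0, VH = -40,
    VtauHhalf = -105, kTauH = 10, tauHmin = 1000, tauHmax = 6000,
    Ca0 = 0.1, tauCa = 25, F = 96500, r0 = 4e-4, r1 = 0.25e-4)
  p <- new("CellularParams", values = v)
  if (...length()) p <- setParams(p, ...)
  p
}

#' Background synaptic bombardment parameters (in-vivo-like conditions)
#'
#' Stochastic AMPA, NMDA, GABA-A and GABA-B opening probabilities follow
#' Ornstein-Uhlenbeck processes whose means equal the steady state of the
#' corresponding first- or second-order synaptic kinetics driven by
#' \code{nExc} (resp. \code{nInh}) presynaptic neurons firing at
#' \code{fExc} (\code{fInh}) Hz, and whose standard deviations are half the
#' means. Inhibitory maximal conductances are balanced against excitation
#' through the driving-force / input-count relation (see
#' \code{\link{configureBackground}}).
#'
#' @param ... parameter overrides by name.
#' @return An \linkS4class{OUBackgroundParams} (call
#'   \code{\link{configureBackground}} to fill the derived fields).
#' @export
ouBackgroundParams <- function(...) {
  v <- list(
    gAMPA = 0.02, tauAMPAdecay = 2.5,
    gNMDA = 0.03, alphaNMDA = 0.275, tauNMDArise = 4.65, tauNMDAdecay = 75,
    gGABAA = 0.0063, tauGABAAdecay = 10,
    gGABAB = 3.125e-4, alphaGABAB = 0.015, tauGABABrise = 90,
    tauGABABdecay = 160,
    VAMPA = 0, VNMDA = 0, VGABAA = -70, VGABAB = -90,
    deltaP = 0.1, nExc = 484, nInh = 121, fExc = 7, fInh = 7,
    Mg = 1.5, Vmean = -57.5,
    # derived by configureBackground
    mAMPA = NA, mNMDA = NA, mGABAA = NA, mGABAB = NA,
    sigmaAMPA = NA, sigmaNMDA = NA, sigmaGABAA = NA, sigmaGABAB = NA,
    gGABAAbar = NA, gGABABbar = NA)
  p <- new("OUBackgroundParams", values = v)
  if (...length()) p <- setParams(p, ...)
  p
}

#' Complete a background parameter set
#'
#' Fills the OU means from the synaptic steady states, sets sigma = m / 2,
#' and solves the excitation/inhibition balance for the GABA-A and GABA-B
#' maximal conductances:
#' \deqn{\bar g_{GABA_x} = g_{GABA_x} \frac{-(V_{mean} - V_{Exc})}{(V_{mean} -
#'   V_{GABA_x})} \frac{n_{Exc}}{n_{Inh}}}
#' First-order steady state (AMPA, GABA-A):
#' m = (1 + (tau_decay dp f n)^-1)^-1 with f per ms; second-order (NMDA,
#' GABA-B): m = (1 + (tau_decay alpha)^-1 (1 + (tau_rise dp f n)^-1))^-1.
#'
#' @param p an \linkS4class{OUBackgroundParams}.
#' @return The completed parameter set.
#' @export
configureBackground <- function(p) {
  v <- paramList(p)
  if (v$fExc <= 0 || v$nExc <= 0 || v$fInh <= 0 || v$nInh <= 0)
    stop("presynaptic rate and count must be positive (balance degenerate)")
  m1 <- function(tauD, dp, fHz, n) 1 / (1 + 1 / (tauD * dp * (fHz / 1000) * n))
  m2 <- function(tauD, alpha, tauR, dp, fHz, n)
    1 / (1 + (1 / (tauD * alpha)) * (1 + 1 / (tauR * dp * (fHz / 1000) * n)))
  mA <- m1(v$tauAMPAdecay, v$deltaP, v$fExc, v$nExc)
  mN <- m2(v$tauNMDAdecay, v$alphaNMDA, v$tauNMDArise, v$deltaP, v$fExc, v$nExc)
  mGA <- m1(v$tauGABAAdecay, v$deltaP, v$fInh, v$nInh)
  mGB <- m2(v$tauGABABdecay, v$alphaGABAB, v$tauGABABrise, v$deltaP, v$fInh,
            v$nInh)
  ratio <- v$nExc / v$nInh
  drive <- -(v$Vmean - v$VAMPA)
  setParams(p,
            mAMPA = mA, mNMDA = mN, mGABAA = mGA, mGABAB = mGB,
            sigmaAMPA = 0.5 * mA, sigmaNMDA = 0.5 * mN,
            sigmaGABAA = 0.5 * mGA, sigmaGABAB = 0.5 * mGB,
            gGABAAbar = v$gGABAA * drive / (v$Vmean - v$VGABAA) * ratio,
            gGABABbar = v$gGABAB * drive / (v$Vmean - v$VGABAB) * ratio)
}

#' Simulate the single-cell model under background bombardment
#'
#' Forward-Euler integration (default dt = 0.1 ms) of the full
#' Hodgkin-Huxley model with OU-fluctuating synaptic opening probabilities
#' (exact OU update, reflected at [0, 1]). Spikes are detected as upward
#' crossings of -20 mV, well inside the action-potential upstroke.
#'
#' @param p a \linkS4class{CellularParams}.
#' @param bg a configured \linkS4class{OUBackgroundParams}; run through
#'   \code{\link{configureBackground}} automatically when the derived fields
#'   are missing.
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @param seed integer seed for the OU noise.
#' @param traces also return V, Ca and gating traces (memory-heavy).
#' @return list with \code{train} (a \linkS4class{SpikeTrain}) and, when
#'   requested, \code{traces}.
#' @export
simulateCell <- function(p, bg = ouBackgroundParams(), duration = 6e5,
                         dt = 0.1, seed = 1, traces = FALSE) {
  if (is.na(bg$mAMPA)) bg <- configureBackground(bg)
  v <- paramList(bg)
  bgList <- list(
    gAMPA = v$gAMPA, gNMDA = v$gNMDA,
    gGABAAbar = v$gGABAAbar, gGABABbar = v$gGABABbar,
    VAMPA = v$VAMPA, VNMDA = v$VNMDA, VGABAA = v$VGABAA, VGABAB = v$VGABAB,
    Mg = v$Mg,
    m = c(v$mAMPA, v$mNMDA, v$mGABAA, v$mGABAB),
    sigma = c(v$sigmaAMPA, v$sigmaNMDA, v$sigmaGABAA, v$sigmaGABAB),
    tauDecay = c(v$tauAMPAdecay, v$tauNMDAdecay, v$tauGABAAdecay,
                 v$tauGABABdecay))
  res <- .cell_simulate(paramList(p), bgList, duration, dt,
                        as.numeric(seed), traces)
  train <- SpikeTrain(res$spikes, tStart = 0, tStop = duration,
                      unitId = sprintf("cell_seed%d", as.integer(seed)))
  out <- list(train = train, V_end = res$V_end)
  if (traces)
    out$traces <- data.frame(t = seq_len(length(res$V)) * dt, V = res$V,
                             Ca = res$Ca, pCAN = res$pCAN, pAHP = res$pAHP)
  out
}

#' NMDA magnesium-block factor
#'
#' x(V) = (1 + [Mg] exp(-0.062 V) / 3.57)^-1.
#'
#' @param V membrane potential (mV).
#' @param Mg magnesium concentration (mM).
#' @export
nmdaMgBlock <- function(V, Mg = 1.5) 1 / (1 + Mg * exp(-0.062 * V) / 3.57)

#' Parametric sweep of the cellular model
#'
#' Simulates the cell on a grid of parameter couples (by default
#' (gCAN, gAHP)), extracts the temporal signature of each run, and flags
#' grid points whose mean firing rate exceeds the 20 Hz realism bound as
#' discarded.
#'
#' @param grid data.frame whose columns name cellular parameters; one row
#'   per grid point.
#' @param p,bg base parameter sets.
#' @param duration per-run duration (ms).
#' @param reps repetitions per grid point (seeds \code{seed + 0:(reps-1)}).
#' @param seed base seed.
#' @param minSpikes passed to \code{\link{extractSignature}}.
#' @param maxRate realism bound (Hz).
#' @return data.frame: grid columns, rep, LAT_ms, TAU_ms, rate_hz,
#'   discarded, valid.
#' @export
sweepCellular <- function(grid, p = cellularParams(),
                          bg = ouBackgroundParams(), duration = 6e5,
                          reps = 1, seed = 1, minSpikes = 1000,
                          maxRate = 20) {
  if (is.na(bg$mAMPA)) bg <- configureBackground(bg)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    pg <- do.call(setParams, c(list(p), as.list(grid[g, , drop = FALSE])))
    for (r in seq_len(reps)) {
      s <- seed + (g - 1) * reps + (r - 1)
      sim <- simulateCell(pg, bg, duration = duration, seed = s)
      rate <- 1000 * length(spikeTimes(sim$train)) / duration
      sig <- extractSignature(sim$train, minSpikes = minSpikes, seed = s)
      rows[[length(rows) + 1]] <- cbind(
        grid[g, , drop = FALSE],
        data.frame(rep = r, LAT_ms = latValue(sig), TAU_ms = tauValue(sig),
                   rate_hz = rate, discarded = rate > maxRate,
                   valid = isValid(sig)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
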