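#' Specification of a state-substitution perturbation
#'
#' @param population "Exc" or "Inh": the population whose dynamical state is
#'   substituted.
#' @param fraction fraction of that population substituted (0 gives the
#'   unperturbed control).
#' @param snapshotOffset time after period onset at which states are taken
#'   and perturbations applied (ms).
#' @param minPeriod only periods longer than this qualify (ms).
#' @param nCombos random period-pair combinations per state pair.
#' @return list of settings.
#' @export
perturbationSpec <- function(population = c("Inh", "Exc"), fraction = 0.02,
                             snapshotOffset = 50, minPeriod = 100,
                             nCombos = 50) {
  population <- match.arg(population)
  stopifnot(fraction >= 0, fraction <= 1)
  list(population = population, fraction = fraction,
       snapshotOffset = snapshotOffset, minPeriod = minPeriod,
       nCombos = nCombos)
}

# periods qualifying as perturbation sources/targets
.qualifyingPeriods <- function(seq, minPeriod = 100) {
  per <- statePeriods(seq)
  per[per$state > 0 & per$duration > minPeriod, , drop = FALSE]
}

# substitute the dynamical state of `idx` (1-based neurons) in snapshot A
# by their values in snapshot B; derived synaptic sums are recomputed
.substituteState <- function(A, B, idx) {
  if (!length(idx)) return(A)
  out <- A
  for (f in c("V", "Ca", "pCAN", "pAHP", "pA", "qN", "pN", "pGA", "qB",
              "pB"))
    out[[f]][idx] <- B[[f]][idx]
  out$ref[idx] <- B$ref[idx]
  # pending spikes (0-based in snapshots): selected neurons take B's flags
  pa <- setdiff(A$pending, idx - 1L)
  pb <- intersect(B$pending, idx - 1L)
  out$pending <- as.integer(sort(c(pa, pb)))
  out$sA <- NULL; out$sGA <- NULL  # force recomputation from p vectors
  out
}

# decode a simulated segment with frozen HMM parameters, starting from the
# posterior state distribution of the original run at the perturbation bin;
# with multinomial emissions the selection among simultaneous spikes is
# re-drawn (seeded), the stochasticity behind nonzero basal transition rates
.decodeSegment <- function(sim, hmm, initProb, threshold = 0.8, seed = NULL) {
  csr <- .toCSR(sim, binWidth = hmm@binWidth)
  post <- if (identical(hmm@emissionType, "multinomial")) {
    sym <- withSeed(seed, .csrSymbols(csr))
    .hmm_posteriors_multi(sym, hmm@transition, hmm@emission, initProb)
  } else {
    .hmm_posteriors(csr$spk, csr$ptr, csr$nNeurons, hmm@transition,
                    hmm@emission, initProb)
  }
  decodeStates(post, threshold = threshold, binWidth = hmm@binWidth)
}

#' Run one state-substitution perturbation
#'
#' Takes the network state 50 ms after the onset of an ongoing-state period,
#' substitutes the dynamical variables (membrane potential, refractory and
#' pending-spike state, calcium, intrinsic gating, synaptic opening
#' variables) of a random subset of the chosen population with their values
#' 50 ms after the onset of a target-state period, resumes the simulation to
#' the end of the original ongoing period, decodes the resumed segment with
#' the frozen HMM of the unperturbed run, and reports the proportion of
#' segment time spent outside the ongoing state (escape) and inside the
#' target state (reach).
#'
#' @param p,syn network parameters and synaptic matrix of the original run.
#' @param hmm the \linkS4class{HMMFit} of the unperturbed simulation.
#' @param snapA,snapB state snapshots at (ongoing, target) period onsets +
#'   offset.
#' @param ongoingState,targetState state labels (1-based).
#' @param segmentDuration time from perturbation to the end of the ongoing
#'   period (ms).
#' @param initProb posterior state distribution at the perturbation time in
#'   the original run.
#' @param spec a \code{\link{perturbationSpec}}.
#' @param seed seed for the random subset.
#' @return list(escape, reach, labels).
#' @export
runPerturbation <- function(p, syn, hmm, snapA, snapB, ongoingState,
                            targetState, segmentDuration, initProb, spec,
                            seed = 1) {
  stopifnot(ongoingState != targetState)
  pop <- if (spec$population == "Exc") which(syn@isExc) else
    which(!syn@isExc)
  nSub <- round(spec$fraction * length(pop))
  idx <- if (nSub > 0) withSeed(seed, sample(pop, nSub)) else integer(0)
  init <- .substituteState(snapA, snapB, idx)
  sim <- simulateNetwork(p, syn, duration = segmentDuration, init = init)
  seg <- .decodeSegment(sim, hmm, initProb, seed = seed + 1L)
  lab <- stateLabels(seg)
  list(escape = mean(lab != ongoingState), reach = mean(lab == targetState),
       labels = lab)
}

#' Prepare a network for perturbation runs
#'
#' Simulates the network, fits the HMM, decodes states, and re-runs the
#' identical (deterministic) simulation capturing full state snapshots
#' 50 ms after the onset of every qualifying period.
#'
#' @param p network parameters.
#' @param seed network/initial-condition seed.
#' @param duration unperturbed simulation length (ms).
#' @param cfg an \code{\link{hmmConfig}}.
#' @param spec a \code{\link{perturbationSpec}} (for the qualifying rule).
#' @param syn optional prebuilt \linkS4class{SynapticMatrix}.
#' @param emission emission family passed to \code{\link{fitHMM}}.
#' @return list(p, syn, sim, hmm, seq, periods, snapshots, snapshotTimes).
#' @export
preparePerturbation <- function(p, seed = 1, duration = 6e5,
                                cfg = hmmConfig(), spec = perturbationSpec(),
                                syn = NULL, emission = "bernoulli") {
  if (is.null(syn)) syn <- buildNetwork(p, seed = seed)
  sim <- simulateNetwork(p, syn, duration = duration, seed = seed + 1e4)
  hmm <- fitHMM(sim, cfg, seed = seed, emission = emission)
  seq <- decodeStates(hmm, threshold = cfg$threshold)
  per <- .qualifyingPeriods(seq, spec$minPeriod)
  snapTimes <- per$t0 + spec$snapshotOffset
  sim2 <- simulateNetwork(p, syn, duration = duration, seed = seed + 1e4,
                          snapshotTimes = snapTimes)
  list(p = p, syn = syn, sim = sim, hmm = hmm, seq = seq, periods = per,
       snapshots = sim2@snapshots, snapshotTimes = snapTimes)
}

#' Escape/reach curves over substitution fractions
#'
#' For each network seed, population and fraction, runs the perturbation
#' protocol over random combinations of (ongoing, target) period pairs for
#' every ordered pair of distinct HMM states, and averages the escape and
#' reach probabilities. Basal probabilities are estimated from the
#' fraction-0 runs and both offset-only and offset-normalized
#' ((raw - basal)/(1 - basal), clipped at 0) curves are reported.
#'
#' @param p network parameters (MCCm preset for the published protocol).
#' @param networkSeeds seeds, one per network instance.
#' @param fractions substitution-fraction grid (0 is added when missing, to
#'   estimate basal rates).
#' @param populations populations to test.
#' @param nCombos period-pair combinations per state pair.
#' @param duration unperturbed simulation length (ms).
#' @param cfg an \code{\link{hmmConfig}}.
#' @param seed master seed for combination draws.
#' @param emission emission family passed to \code{\link{fitHMM}}.
#' @return list(runs = per-run data.frame, curves = summary data.frame with
#'   raw, offset and normalized escape/reach per population and fraction,
#'   basalEscape, basalReach).
#' @export
transitionSweep <- function(p, networkSeeds = 1, fractions = c(0, 0.02),
                            populations = c("Inh", "Exc"), nCombos = 10,
                            duration = 6e5, cfg = hmmConfig(), seed = 1,
                            emission = "bernoulli") {
  if (!0 %in% fractions) fractions <- c(0, fractions)
  fractions <- sort(unique(fractions))
  runs <- list()
  for (ns in networkSeeds) {
    prep <- preparePerturbation(p, seed = ns, duration = duration,
                                cfg = cfg,
                                spec = perturbationSpec(nCombos = nCombos),
                                emission = emission)
    per <- prep$periods
    statesPresent <- sort(unique(per$state))
    if (length(statesPresent) < 2) {
      warning("network seed ", ns,
              " lacks two states with qualifying periods; skipped")
      next
    }
    binW <- prep$hmm@binWidth
    pairs <- expand.grid(a = statesPresent, b = statesPresent)
    pairs <- pairs[pairs$a != pairs$b, ]
    comboSeed <- seed
    for (pi in seq_len(nrow(pairs))) {
      a <- pairs$a[pi]; b <- pairs$b[pi]
      perA <- per[per$state == a, , drop = FALSE]
      perB <- per[per$state == b, , drop = FALSE]
      nc <- min(nCombos, nrow(perA) * nrow(perB))
      draw <- withSeed(comboSeed + pi, data.frame(
        ia = sample.int(nrow(perA), nc, replace = TRUE),
        ib = sample.int(nrow(perB), nc, replace = TRUE)))
      for (ci in seq_len(nc)) {
        rowA <- perA[draw$ia[ci], ]; rowB <- perB[draw$ib[ci], ]
        tPert <- rowA$t0 + 50
        segDur <- rowA$t1 - tPert
        keyA <- SpikeDynamics:::.snapKey(tPert)
        keyB <- SpikeDynamics:::.snapKey(rowB$t0 + 50)
        if (!keyA %in% names(prep$snapshots) ||
            !keyB %in% names(prep$snapshots)) next
        binAt <- min(as.integer(tPert / binW) + 1L,
                     nrow(prep$hmm@posteriors))
        initProb <- prep$hmm@posteriors[binAt, ]
        for (popn in populations) for (fr in fractions) {
          spec <- perturbationSpec(population = popn, fraction = fr,
                                   nCombos = nCombos)
          res <- runPerturbation(p, prep$syn, prep$hmm,
                                 prep$snapshots[[keyA]],
                                 prep$snapshots[[keyB]], a, b, segDur,
                                 initProb, spec,
                                 seed = seed + 1000 * pi + ci)
          runs[[length(runs) + 1]] <- data.frame(
            network = ns, population = popn, fraction = fr, ongoing = a,
            target = b, combo = ci, escape = res$escape,
            reach = res$reach, segDur = segDur)
        }
      }
    }
  }
  runs <- do.call(rbind, runs)
  if (is.null(runs)) stop("no perturbation runs completed")
  agg <- stats::aggregate(cbind(escape, reach) ~ population + fraction,
                          runs, mean)
  basal <- agg[agg$fraction == 0, ]
  basalEscape <- mean(basal$escape)
  basalReach <- mean(basal$reach)
  agg$escape_offset <- pmax(agg$escape - basalEscape, 0)
  agg$reach_offset <- pmax(agg$reach - basalReach, 0)
  agg$escape_norm <- pmax((agg$escape - basalEscape) / (1 - basalEscape), 0)
  agg$reach_norm <- pmax((agg$reach - basalReach) / (1 - basalReach), 0)
  sem <- stats::aggregate(cbind(escape, reach) ~ population + fraction,
                          runs,
                          function(v) stats::sd(v) / sqrt(length(v)))
  names(sem)[3:4] <- c("escape_sem", "reach_sem")
  curves <- merge(agg, sem, by = c("population", "fraction"))
  list(runs = runs, curves = curves, basalEscape = basalEscape,
       basalReach = basalReach)
}
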