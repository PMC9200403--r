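#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <set>
#include <string>
#include <vector>
using namespace Rcpp;

// Deterministic standard normals: Box-Muller over a 64-bit Mersenne twister,
// so simulations are bit-reproducible across platforms irrespective of the
// C++ library's normal_distribution implementation.
struct GaussRng {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit GaussRng(uint64_t seed) : eng(seed) {}
  double unif() {
    // in (0, 1]
    return (static_cast<double>(eng() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

static inline double mg_block(double V, double Mg) {
  return 1.0 / (1.0 + Mg * std::exp(-0.062 * V) / 3.57);
}

// Action-potential gating: Boltzmann steady states with fixed time
// constants, tuned so the model's Na/K maximal conductances produce
// stereotyped full-height spikes with reliable repolarization at dt=0.1 ms.
static inline double m_inf(double V) { return 1.0 / (1.0 + std::exp(-(V + 42.0) / 5.0)); }
static inline double h_inf(double V) { return 1.0 / (1.0 + std::exp((V + 50.0) / 4.0)); }
static inline double n_inf(double V) { return 1.0 / (1.0 + std::exp(-(V + 45.0) / 4.0)); }
static const double TAU_M = 0.5, TAU_H = 2.0, TAU_N = 2.0;

// [[Rcpp::export(name = ".cell_simulate")]]
List cell_simulate(List par, List bg, double duration, double dt,
                   uint64_t seed, bool traces) {
  // --- unpack cellular parameters ---------------------------------------
  const double C = as<double>(par["C"]);
  const double gL = as<double>(par["gL"]), VL = as<double>(par["VL"]);
  const double gNa = as<double>(par["gNa"]), VNa = as<double>(par["VNa"]);
  const double gK = as<double>(par["gK"]), VK = as<double>(par["VK"]);
  const double gCaL = as<double>(par["gCaL"]), VCaL = as<double>(par["VCaL"]);
  const double vhCaL = as<double>(par["VhalfCaL"]), kCaLs = as<double>(par["kCaL"]);
  const double aCaL = as<double>(par["alphaCaL"]), bCaL = as<double>(par["betaCaL"]);
  const double gCAN = as<double>(par["gCAN"]), VCAN = as<double>(par["VCAN"]);
  const double aCAN = as<double>(par["alphaCAN"]), bCAN = as<double>(par["betaCAN"]);
  const double gAHP = as<double>(par["gAHP"]), VAHP = as<double>(par["VAHP"]);
  const double aAHP = as<double>(par["alphaAHP"]), bAHP = as<double>(par["betaAHP"]);
  const double gCaT = as<double>(par["gCaT"]), VCaT = as<double>(par["VCaT"]);
  const double gH = as<double>(par["gH"]), VH = as<double>(par["VH"]);
  const double vhTauH = as<double>(par["VtauHhalf"]), kTauH = as<double>(par["kTauH"]);
  const double tauHmin = as<double>(par["tauHmin"]), tauHmax = as<double>(par["tauHmax"]);
  const double Ca0 = as<double>(par["Ca0"]), tauCa = as<double>(par["tauCa"]);
  const double Fconst = as<double>(par["F"]);
  const double r0 = as<double>(par["r0"]), r1 = as<double>(par["r1"]);

  // surface/volume ratio of the sub-membrane calcium shell
  const double SoV = 1.0 / (r1 * (1.0 - r1 / r0 + r1 * r1 / (3.0 * r0 * r0)));
  const double kCa = SoV / (2.0 * Fconst); // uM/ms per uA/cm^2

  // --- background synaptic OU parameters --------------------------------
  const double gA = as<double>(bg["gAMPA"]), gN = as<double>(bg["gNMDA"]);
  const double gGA = as<double>(bg["gGABAAbar"]), gGB = as<double>(bg["gGABABbar"]);
  const double VA = as<double>(bg["VAMPA"]), VN = as<double>(bg["VNMDA"]);
  const double VGA = as<double>(bg["VGABAA"]), VGB = as<double>(bg["VGABAB"]);
  const double Mg = as<double>(bg["Mg"]);
  NumericVector mOU = as<NumericVector>(bg["m"]);     // AMPA, NMDA, GABAA, GABAB
  NumericVector sg = as<NumericVector>(bg["sigma"]);
  NumericVector tdec = as<NumericVector>(bg["tauDecay"]);

  const int nSteps = static_cast<int>(std::round(duration / dt));
  GaussRng rng(seed);

  // state
  double V = VL, Ca = Ca0;
  double mNa = m_inf(V), h = h_inf(V), n = n_inf(V);
  double pCaLv = 1.0 / (1.0 + std::exp(-(V - vhCaL) / kCaLs));
  double pCAN = aCAN * Ca / (aCAN * Ca + bCAN);
  double pAHP = aAHP * Ca / (aAHP * Ca + bAHP);
  double hCaT = 1.0 / (1.0 + std::exp((V + 80.0) / 5.0));
  double rH = 1.0 / (1.0 + std::exp((V + 80.0) / 6.0));
  double p[4];
  double edec[4], snoise[4];
  for (int x = 0; x < 4; ++x) {
    p[x] = mOU[x];
    edec[x] = std::exp(-dt / tdec[x]);
    snoise[x] = sg[x] * std::sqrt(1.0 - edec[x] * edec[x]);
  }

  std::vector<double> spikes;
  const double thresholdDetect = -20.0;
  bool above = V > thresholdDetect;

  const int keep = traces ? nSteps : 0;
  NumericVector trV(keep), trCa(keep), trCAN(keep), trAHP(keep);

  for (int s = 0; s < nSteps; ++s) {
    // ionic currents at current state
    double INa = gNa * mNa * mNa * mNa * h * (V - VNa);
    double IK = gK * n * n * n * n * (V - VK);
    double IL = gL * (V - VL);
    double ICaL = gCaL * pCaLv * pCaLv * (V - VCaL);
    double ICAN = gCAN * pCAN * (V - VCAN);
    double IAHP = gAHP * pAHP * pAHP * (V - VAHP);
    double mCaT = 1.0 / (1.0 + std::exp(-(V + 52.0) / 7.4));
    double ICaT = gCaT * mCaT * mCaT * hCaT * (V - VCaT);
    double IH = gH * rH * (V - VH);
    double IA = gA * p[0] * (V - VA);
    double IN = gN * p[1] * mg_block(V, Mg) * (V - VN);
    double IGA = gGA * p[2] * (V - VGA);
    double IGB = gGB * p[3] * (V - VGB);
    double Iion = IL + INa + IK + ICaL + ICAN + IAHP + ICaT + IH;
    double Isyn = IA + IN + IGA + IGB;

    double Vnew = V + dt * (-(Iion + Isyn) / C);
    if (!std::isfinite(Vnew) || std::fabs(Vnew) > 200.0)
      stop("numerical blow-up (|V| > 200 mV) at t = %f ms", s * dt);

    // gating updates (forward Euler)
    mNa += dt * (m_inf(V) - mNa) / TAU_M;
    h += dt * (h_inf(V) - h) / TAU_H;
    n += dt * (n_inf(V) - n) / TAU_N;
    double pCaLinf = 1.0 / (1.0 + std::exp(-(V - vhCaL) / kCaLs));
    double tauCaL = 10.0 / std::max(aCaL + bCaL * V, 1e-3);
    tauCaL = std::max(tauCaL, 0.1);
    pCaLv += dt * (pCaLinf - pCaLv) / tauCaL;
    pCAN += dt * (aCAN * Ca * (1.0 - pCAN) - bCAN * pCAN);
    pAHP += dt * (aAHP * Ca * (1.0 - pAHP) - bAHP * pAHP);
    double hCaTinf = 1.0 / (1.0 + std::exp((V + 80.0) / 5.0));
    hCaT += dt * (hCaTinf - hCaT) / 30.0;
    double rHinf = 1.0 / (1.0 + std::exp((V + 80.0) / 6.0));
    double tauH = tauHmin + (tauHmax - tauHmin) /
      (1.0 + std::exp(-(V - vhTauH) / kTauH));
    rH += dt * (rHinf - rH) / tauH;
    Ca += dt * (-kCa * (ICaL + ICaT) + (Ca0 - Ca) / tauCa);
    if (Ca < 0.0) Ca = 0.0;
    // clamp gating to [0, 1]
    if (mNa < 0) mNa = 0; else if (mNa > 1) mNa = 1;
    if (h < 0) h = 0; else if (h > 1) h = 1;
    if (n < 0) n = 0; else if (n > 1) n = 1;
    if (pCaLv < 0) pCaLv = 0; else if (pCaLv > 1) pCaLv = 1;
    if (pCAN < 0) pCAN = 0; else if (pCAN > 1) pCAN = 1;
    if (pAHP < 0) pAHP = 0; else if (pAHP > 1) pAHP = 1;
    if (hCaT < 0) hCaT = 0; else if (hCaT > 1) hCaT = 1;
    if (rH < 0) rH = 0; else if (rH > 1) rH = 1;

    // exact OU update; reflection at [0, 1]
    for (int x = 0; x < 4; ++x) {
      double noise = (snoise[x] > 0.0) ? snoise[x] * rng.norm() : 0.0;
      p[x] = mOU[x] + (p[x] - mOU[x]) * edec[x] + noise;
      if (p[x] < 0.0) p[x] = -p[x];
      if (p[x] > 1.0) p[x] = 2.0 - p[x];
      if (p[x] < 0.0) p[x] = 0.0; // pathological sigma
    }

    V = Vnew;
    // spike: upward crossing of the detection threshold
    if (!above && V > thresholdDetect) { spikes.push_back((s + 1) * dt); above = true; }
    else if (above && V < thresholdDetect) above = false;

    if (traces) { trV[s] = V; trCa[s] = Ca; trCAN[s] = pCAN; trAHP[s] = pAHP; }
  }

  List out = List::create(_["spikes"] = wrap(spikes), _["V_end"] = V);
  if (traces) {
    out["V"] = trV; out["Ca"] = trCa; out["pCAN"] = trCAN; out["pAHP"] = trAHP;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Recurrent conductance-based LIF network
// Wt is the N x N weight matrix stored post-major: Wt(j, i) = w(i -> j), so
// column i holds the outgoing weights of presynaptic neuron i (contiguous).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".net_simulate")]]
List net_simulate(NumericMatrix Wt, LogicalVector isExc,
                  NumericVector gGAbal, NumericVector gGBbal,
                  List par, int nSteps, double dt, List init,
                  IntegerVector snapshotSteps, bool recordSpikes) {
  const int N = Wt.nrow();
  if (Wt.ncol() != N) stop("Wt must be square");

  const double C = as<double>(par["C"]);
  const double gL = as<double>(par["gL"]), VL = as<double>(par["VL"]);
  const double theta = as<double>(par["theta"]), Vrest = as<double>(par["Vrest"]);
  const int refSteps = as<int>(par["refSteps"]);
  const double gCAN = as<double>(par["gCAN"]), VCAN = as<double>(par["VCAN"]);
  const double aCAN = as<double>(par["alphaCAN"]), bCAN = as<double>(par["betaCAN"]);
  const double gAHP = as<double>(par["gAHP"]), VAHP = as<double>(par["VAHP"]);
  const double aAHP = as<double>(par["alphaAHP"]), bAHP = as<double>(par["betaAHP"]);
  const double Ca0 = as<double>(par["Ca0"]), tauCa = as<double>(par["tauCa"]);
  const double dCaInc = as<double>(par["deltaCa"]);
  const double gAMPA = as<double>(par["gAMPA"]), gNMDA = as<double>(par["gNMDA"]);
  const double VA = as<double>(par["VAMPA"]), VN = as<double>(par["VNMDA"]);
  const double VGA = as<double>(par["VGABAA"]), VGB = as<double>(par["VGABAB"]);
  const double tauA = as<double>(par["tauAMPA"]), tauGA = as<double>(par["tauGABAA"]);
  const double tauNr = as<double>(par["tauNMDArise"]), tauNd = as<double>(par["tauNMDAdecay"]);
  const double aN = as<double>(par["alphaNMDA"]);
  const double tauBr = as<double>(par["tauGABABrise"]), tauBd = as<double>(par["tauGABABdecay"]);
  const double aB = as<double>(par["alphaGABAB"]);
  const double dx = as<double>(par["deltaX"]);
  const double Mg = as<double>(par["Mg"]);
  const double gFF = as<double>(par["gAMPAFF"]) * as<double>(par["pAMPAFF"]);

  // state vectors (copied from init so the caller's snapshot is untouched)
  NumericVector V = clone(as<NumericVector>(init["V"]));
  IntegerVector ref = clone(as<IntegerVector>(init["ref"]));
  NumericVector Ca = clone(as<NumericVector>(init["Ca"]));
  NumericVector pCAN = clone(as<NumericVector>(init["pCAN"]));
  NumericVector pAHP = clone(as<NumericVector>(init["pAHP"]));
  NumericVector pA = clone(as<NumericVector>(init["pA"]));
  NumericVector qN = clone(as<NumericVector>(init["qN"]));
  NumericVector pN = clone(as<NumericVector>(init["pN"]));
  NumericVector pGA = clone(as<NumericVector>(init["pGA"]));
  NumericVector qB = clone(as<NumericVector>(init["qB"]));
  NumericVector pB = clone(as<NumericVector>(init["pB"]));
  IntegerVector pending0 = as<IntegerVector>(init["pending"]);

  // running postsynaptic sums for first-order receptors; restored from the
  // snapshot when present (bit-identical resume), else derived from p
  NumericVector sA(N), sGA(N);
  const double* wt = REAL(Wt);
  bool haveSums = init.containsElementNamed("sA");
  if (haveSums) {
    sA = clone(as<NumericVector>(init["sA"]));
    sGA = clone(as<NumericVector>(init["sGA"]));
  } else {
    for (int i = 0; i < N; ++i) {
      double c = isExc[i] ? pA[i] : pGA[i];
      if (c == 0.0) continue;
      const double* col = wt + static_cast<size_t>(i) * N;
      if (isExc[i]) for (int j = 0; j < N; ++j) sA[j] += col[j] * c;
      else          for (int j = 0; j < N; ++j) sGA[j] += col[j] * c;
    }
  }

  std::vector<int> pending(pending0.begin(), pending0.end()); // 0-based
  std::vector<int> spkNeuron; std::vector<int> spkStep;
  std::vector<double> sN(N), sB(N);

  const double decA = 1.0 - dt / tauA, decGA = 1.0 - dt / tauGA;
  const double decNr = 1.0 - dt / tauNr, decBr = 1.0 - dt / tauBr;

  std::set<int> snapSet(snapshotSteps.begin(), snapshotSteps.end());
  List snapshots;
  std::vector<std::string> snapNames;

  auto takeSnapshot = [&](int step) {
    List st = List::create(
      _["V"] = clone(V), _["ref"] = clone(ref), _["Ca"] = clone(Ca),
      _["pCAN"] = clone(pCAN), _["pAHP"] = clone(pAHP),
      _["pA"] = clone(pA), _["qN"] = clone(qN), _["pN"] = clone(pN),
      _["pGA"] = clone(pGA), _["qB"] = clone(qB), _["pB"] = clone(pB),
      _["sA"] = clone(sA), _["sGA"] = clone(sGA),
      _["pending"] = wrap(pending), _["step"] = step);
    snapshots.push_back(st);
    snapNames.push_back(std::to_string(step * dt));
  };

  for (int s = 0; s < nSteps; ++s) {
    if (snapSet.count(s)) takeSnapshot(s);

    // deliver last step's spikes (uniform 1-step synaptic delay)
    for (int idx : pending) {
      const double* col = wt + static_cast<size_t>(idx) * N;
      if (isExc[idx]) {
        double jA = dx * (1.0 - pA[idx]);
        pA[idx] += jA;
        for (int j = 0; j < N; ++j) sA[j] += col[j] * jA;
        qN[idx] += dx * (1.0 - qN[idx]);
      } else {
        double jG = dx * (1.0 - pGA[idx]);
        pGA[idx] += jG;
        for (int j = 0; j < N; ++j) sGA[j] += col[j] * jG;
        qB[idx] += dx * (1.0 - qB[idx]);
      }
    }
    pending.clear();

    // second-order postsynaptic sums (dense pass over presynaptic columns)
    std::fill(sN.begin(), sN.end(), 0.0);
    std::fill(sB.begin(), sB.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      double c = isExc[i] ? pN[i] : pB[i];
      if (c == 0.0) continue;
      const double* col = wt + static_cast<size_t>(i) * N;
      double* out = isExc[i] ? sN.data() : sB.data();
      for (int j = 0; j < N; ++j) out[j] += col[j] * c;
    }

    // membrane update
    for (int j = 0; j < N; ++j) {
      if (ref[j] > 0) { --ref[j]; V[j] = Vrest; continue; }
      double v = V[j];
      double I = gL * (v - VL);
      if (isExc[j]) {
        I += gCAN * pCAN[j] * (v - VCAN);
        I += gAHP * pAHP[j] * pAHP[j] * (v - VAHP);
      }
      I += gAMPA * sA[j] * (v - VA);
      I += gNMDA * sN[j] * mg_block(v, Mg) * (v - VN);
      I += gGAbal[j] * sGA[j] * (v - VGA);
      I += gGBbal[j] * sB[j] * (v - VGB);
      I += gFF * (v - VA);
      double vnew = v + dt * (-I / C);
      if (!std::isfinite(vnew)) stop("non-finite V at step %d", s);
      if (vnew > theta) {
        if (recordSpikes) { spkNeuron.push_back(j + 1); spkStep.push_back(s + 1); }
        V[j] = Vrest;
        ref[j] = refSteps;
        Ca[j] += dCaInc;
        pending.push_back(j);
      } else V[j] = vnew;
    }

    // intrinsic gating and calcium (excitatory neurons carry CAN/AHP)
    for (int j = 0; j < N; ++j) {
      if (isExc[j]) {
        pCAN[j] += dt * (aCAN * Ca[j] * (1.0 - pCAN[j]) - bCAN * pCAN[j]);
        pAHP[j] += dt * (aAHP * Ca[j] * (1.0 - pAHP[j]) - bAHP * pAHP[j]);
        if (pCAN[j] < 0) pCAN[j] = 0; else if (pCAN[j] > 1) pCAN[j] = 1;
        if (pAHP[j] < 0) pAHP[j] = 0; else if (pAHP[j] > 1) pAHP[j] = 1;
      }
      Ca[j] += dt * (Ca0 - Ca[j]) / tauCa;
      if (Ca[j] < 0) Ca[j] = 0;
    }

    // synaptic variable decay / second-order coupling; traces below 1e-30
    // are flushed to zero (physically nothing, and letting them decay
    // through the subnormal range slows the dense pass enormously)
    const double FLUSH = 1e-30;
    for (int i = 0; i < N; ++i) {
      if (isExc[i]) {
        pN[i] += dt * (-pN[i] / tauNd + aN * qN[i] * (1.0 - pN[i]));
        qN[i] *= decNr;
        pA[i] *= decA;
        if (pN[i] < FLUSH) pN[i] = 0.0;
        if (qN[i] < FLUSH) qN[i] = 0.0;
        if (pA[i] < FLUSH) pA[i] = 0.0;
      } else {
        pB[i] += dt * (-pB[i] / tauBd + aB * qB[i] * (1.0 - pB[i]));
        qB[i] *= decBr;
        pGA[i] *= decGA;
        if (pB[i] < FLUSH) pB[i] = 0.0;
        if (qB[i] < FLUSH) qB[i] = 0.0;
        if (pGA[i] < FLUSH) pGA[i] = 0.0;
      }
    }
    for (int j = 0; j < N; ++j) {
      sA[j] *= decA; sGA[j] *= decGA;
      if (sA[j] < FLUSH) sA[j] = 0.0;
      if (sGA[j] < FLUSH) sGA[j] = 0.0;
    }
  }
  if (snapSet.count(nSteps)) takeSnapshot(nSteps);

  List finalState = List::create(
    _["V"] = V, _["ref"] = ref, _["Ca"] = Ca, _["pCAN"] = pCAN,
    _["pAHP"] = pAHP, _["pA"] = pA, _["qN"] = qN, _["pN"] = pN,
    _["pGA"] = pGA, _["qB"] = qB, _["pB"] = pB, _["sA"] = sA,
    _["sGA"] = sGA, _["pending"] = wrap(pending), _["step"] = nSteps);
  snapshots.attr("names") = wrap(snapNames);
  return List::create(
    _["spikeNeuron"] = wrap(spkNeuron), _["spikeStep"] = wrap(spkStep),
    _["snapshots"] = snapshots, _["finalState"] = finalState);
}
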