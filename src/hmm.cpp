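#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bernoulli-emission HMM over binarized population rasters at fine time bins.
// The raster is passed in compressed form: spikeNeuron holds the (0-based)
// indices of the neurons that spiked in each bin, binPtr (length T + 1) the
// CSR offsets into it. With 0.5-ms bins spikes are sparse, so per-bin
// emission log-likelihoods cost O(spikes) on top of a per-state constant.

static void emissionLogLik(const std::vector<int>& spk,
                           const std::vector<int>& ptr,
                           const NumericMatrix& emis, // K x N
                           std::vector<double>& ll) { // T x K, row-major
  const int K = emis.nrow(), N = emis.ncol();
  const int T = static_cast<int>(ptr.size()) - 1;
  std::vector<double> base(K, 0.0);
  std::vector<double> lodds(static_cast<size_t>(K) * N);
  for (int k = 0; k < K; ++k)
    for (int n = 0; n < N; ++n) {
      double p = emis(k, n);
      base[k] += std::log1p(-p);
      lodds[static_cast<size_t>(k) * N + n] = std::log(p) - std::log1p(-p);
    }
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double v = base[k];
      for (int s = ptr[t]; s < ptr[t + 1]; ++s)
        v += lodds[static_cast<size_t>(k) * N + spk[s]];
      ll[static_cast<size_t>(t) * K + k] = v;
    }
}

// Scaled forward-backward. Returns log-likelihood; fills gamma (T x K,
// row-major) and, when learn, the expected transition counts and emission
// sufficient statistics.
static double forwardBackward(const std::vector<double>& ll,
                              const std::vector<int>& spk,
                              const std::vector<int>& ptr,
                              NumericMatrix& trans, NumericVector& initp,
                              std::vector<double>& gamma,
                              bool learn,
                              NumericMatrix* transNew, // K x K counts
                              NumericMatrix* emisNum,  // K x N
                              NumericVector* emisDen) { // K
  const int K = trans.nrow();
  const int T = static_cast<int>(ptr.size()) - 1;
  std::vector<double> alpha(static_cast<size_t>(T) * K);
  std::vector<double> beta(static_cast<size_t>(T) * K);
  std::vector<double> scale(T);
  std::vector<double> b(static_cast<size_t>(T) * K); // emission probs / scale ref
  // per-bin max-normalized emission probabilities to avoid underflow
  for (int t = 0; t < T; ++t) {
    double mx = -1e300;
    for (int k = 0; k < K; ++k) mx = std::max(mx, ll[static_cast<size_t>(t) * K + k]);
    for (int k = 0; k < K; ++k)
      b[static_cast<size_t>(t) * K + k] = std::exp(ll[static_cast<size_t>(t) * K + k] - mx);
    scale[t] = mx; // reuse as the log offset for the likelihood
  }
  double logLik = 0.0;
  // forward
  {
    double c = 0.0;
    for (int k = 0; k < K; ++k) {
      double v = initp[k] * b[k];
      alpha[k] = v; c += v;
    }
    for (int k = 0; k < K; ++k) alpha[k] /= c;
    logLik += std::log(c) + scale[0];
    for (int t = 1; t < T; ++t) {
      c = 0.0;
      for (int k = 0; k < K; ++k) {
        double v = 0.0;
        for (int j = 0; j < K; ++j)
          v += alpha[static_cast<size_t>(t - 1) * K + j] * trans(j, k);
        v *= b[static_cast<size_t>(t) * K + k];
        alpha[static_cast<size_t>(t) * K + k] = v;
        c += v;
      }
      for (int k = 0; k < K; ++k) alpha[static_cast<size_t>(t) * K + k] /= c;
      logLik += std::log(c) + scale[t];
    }
  }
  // backward
  for (int k = 0; k < K; ++k) beta[static_cast<size_t>(T - 1) * K + k] = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    double c = 0.0;
    for (int j = 0; j < K; ++j) {
      double v = 0.0;
      for (int k = 0; k < K; ++k)
        v += trans(j, k) * b[static_cast<size_t>(t + 1) * K + k] *
             beta[static_cast<size_t>(t + 1) * K + k];
      beta[static_cast<size_t>(t) * K + j] = v;
      c += v;
    }
    for (int j = 0; j < K; ++j) beta[static_cast<size_t>(t) * K + j] /= c;
  }
  // gamma
  for (int t = 0; t < T; ++t) {
    double c = 0.0;
    for (int k = 0; k < K; ++k) {
      double v = alpha[static_cast<size_t>(t) * K + k] *
                 beta[static_cast<size_t>(t) * K + k];
      gamma[static_cast<size_t>(t) * K + k] = v;
      c += v;
    }
    for (int k = 0; k < K; ++k) gamma[static_cast<size_t>(t) * K + k] /= c;
  }
  if (learn) {
    // expected transitions
    for (int t = 0; t < T - 1; ++t) {
      double c = 0.0;
      double xi[64];
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k) {
          double v = alpha[static_cast<size_t>(t) * K + j] * trans(j, k) *
                     b[static_cast<size_t>(t + 1) * K + k] *
                     beta[static_cast<size_t>(t + 1) * K + k];
          xi[j * K + k] = v;
          c += v;
        }
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          (*transNew)(j, k) += xi[j * K + k] / c;
    }
    // emission statistics: numerator over spikes, denominator over gamma
    for (int k = 0; k < K; ++k) {
      double tot = 0.0;
      for (int t = 0; t < T; ++t) tot += gamma[static_cast<size_t>(t) * K + k];
      (*emisDen)[k] += tot;
    }
    for (int t = 0; t < T; ++t)
      for (int s = ptr[t]; s < ptr[t + 1]; ++s)
        for (int k = 0; k < K; ++k)
          (*emisNum)(k, spk[s]) += gamma[static_cast<size_t>(t) * K + k];
  }
  return logLik;
}

// [[Rcpp::export(name = ".hmm_em")]]
List hmm_em(IntegerVector spikeNeuron, IntegerVector binPtr, int nNeurons,
            NumericMatrix transInit, NumericMatrix emisInit,
            NumericVector initProb, int maxIter, double tol,
            bool wantPosteriors) {
  const int K = transInit.nrow();
  if (K > 8) stop("at most 8 states supported");
  std::vector<int> spk(spikeNeuron.begin(), spikeNeuron.end());
  std::vector<int> ptr(binPtr.begin(), binPtr.end());
  const int T = static_cast<int>(ptr.size()) - 1;
  NumericMatrix trans = clone(transInit);
  NumericMatrix emis = clone(emisInit);
  NumericVector initp = clone(initProb);

  std::vector<double> ll(static_cast<size_t>(T) * K);
  std::vector<double> gamma(static_cast<size_t>(T) * K);
  double prev = -1e300, logLik = -1e300;
  bool converged = false;
  int it = 0;
  const double pmin = 1e-7, pmax = 1.0 - 1e-7;

  for (it = 0; it < maxIter; ++it) {
    emissionLogLik(spk, ptr, emis, ll);
    NumericMatrix transNew(K, K), emisNum(K, nNeurons);
    NumericVector emisDen(K);
    logLik = forwardBackward(ll, spk, ptr, trans, initp, gamma, true,
                             &transNew, &emisNum, &emisDen);
    if (it > 0 && std::fabs(logLik - prev) <
        tol * (std::fabs(prev) + 1e-10)) { converged = true; break; }
    prev = logLik;
    // M-step
    for (int j = 0; j < K; ++j) {
      double rs = 0.0;
      for (int k = 0; k < K; ++k) rs += transNew(j, k);
      if (rs <= 0.0) { trans(j, j) = 1.0; continue; }
      for (int k = 0; k < K; ++k) trans(j, k) = transNew(j, k) / rs;
    }
    for (int k = 0; k < K; ++k) {
      double den = std::max(emisDen[k], 1e-300);
      for (int n = 0; n < nNeurons; ++n) {
        double p = emisNum(k, n) / den;
        emis(k, n) = std::min(std::max(p, pmin), pmax);
      }
      initp[k] = gamma[k];
    }
    double is = 0.0;
    for (int k = 0; k < K; ++k) is += initp[k];
    for (int k = 0; k < K; ++k) initp[k] /= is;
    Rcpp::checkUserInterrupt();
  }
  // final posteriors under the last parameters
  emissionLogLik(spk, ptr, emis, ll);
  logLik = forwardBackward(ll, spk, ptr, trans, initp, gamma, false,
                           nullptr, nullptr, nullptr);
  List out = List::create(
    _["transition"] = trans, _["emission"] = emis, _["initProb"] = initp,
    _["logLik"] = logLik, _["iterations"] = it, _["converged"] = converged);
  if (wantPosteriors) {
    NumericMatrix post(T, K);
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k)
        post(t, k) = gamma[static_cast<size_t>(t) * K + k];
    out["posteriors"] = post;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Multinomial (one-symbol-per-bin) emission variant: each bin is encoded by
// the identity of the spiking neuron (1..N; ties broken at random upstream)
// or 0 when no neuron spiked. This is the classical population-HMM encoding;
// per-bin evidence is much weaker than the Bernoulli vector, which matters
// for null-state statistics and basal transition rates.
// ---------------------------------------------------------------------------

static void emissionLogLikMulti(const std::vector<int>& sym,
                                const NumericMatrix& emis, // K x (N+1)
                                std::vector<double>& ll) {
  const int K = emis.nrow();
  const int T = static_cast<int>(sym.size());
  NumericMatrix lg(K, emis.ncol());
  for (int k = 0; k < K; ++k)
    for (int s = 0; s < emis.ncol(); ++s) lg(k, s) = std::log(emis(k, s));
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      ll[static_cast<size_t>(t) * K + k] = lg(k, sym[t]);
}

// [[Rcpp::export(name = ".hmm_em_multi")]]
List hmm_em_multi(IntegerVector symbols, int nSymbols,
                  NumericMatrix transInit, NumericMatrix emisInit,
                  NumericVector initProb, int maxIter, double tol,
                  bool wantPosteriors) {
  const int K = transInit.nrow();
  if (K > 8) stop("at most 8 states supported");
  std::vector<int> sym(symbols.begin(), symbols.end());
  const int T = static_cast<int>(sym.size());
  // reuse the shared forward-backward by passing the symbol stream as a
  // one-spike-per-bin CSR (emission stats handled separately below)
  NumericMatrix trans = clone(transInit);
  NumericMatrix emis = clone(emisInit);
  NumericVector initp = clone(initProb);
  std::vector<double> ll(static_cast<size_t>(T) * K);
  std::vector<double> gamma(static_cast<size_t>(T) * K);
  std::vector<int> ptr(T + 1);
  std::vector<int> spk; // unused by the emission stats in this variant
  for (int t = 0; t <= T; ++t) ptr[t] = 0;
  double prev = -1e300, logLik = -1e300;
  bool converged = false;
  int it = 0;
  const double pmin = 1e-8;
  for (it = 0; it < maxIter; ++it) {
    emissionLogLikMulti(sym, emis, ll);
    NumericMatrix transNew(K, K), emisNumDummy(K, 1);
    NumericVector emisDen(K);
    logLik = forwardBackward(ll, spk, ptr, trans, initp, gamma, true,
                             &transNew, &emisNumDummy, &emisDen);
    if (it > 0 && std::fabs(logLik - prev) <
        tol * (std::fabs(prev) + 1e-10)) { converged = true; break; }
    prev = logLik;
    for (int j = 0; j < K; ++j) {
      double rs = 0.0;
      for (int k = 0; k < K; ++k) rs += transNew(j, k);
      if (rs <= 0.0) { trans(j, j) = 1.0; continue; }
      for (int k = 0; k < K; ++k) trans(j, k) = transNew(j, k) / rs;
    }
    // emission M-step over symbols
    NumericMatrix num(K, nSymbols);
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k)
        num(k, sym[t]) += gamma[static_cast<size_t>(t) * K + k];
    for (int k = 0; k < K; ++k) {
      double den = std::max(static_cast<double>(emisDen[k]), 1e-300);
      double tot = 0.0;
      for (int s = 0; s < nSymbols; ++s) {
        double p = std::max(num(k, s) / den, pmin);
        emis(k, s) = p; tot += p;
      }
      for (int s = 0; s < nSymbols; ++s) emis(k, s) /= tot;
      initp[k] = gamma[k];
    }
    double is = 0.0;
    for (int k = 0; k < K; ++k) is += initp[k];
    for (int k = 0; k < K; ++k) initp[k] /= is;
    Rcpp::checkUserInterrupt();
  }
  emissionLogLikMulti(sym, emis, ll);
  logLik = forwardBackward(ll, spk, ptr, trans, initp, gamma, false,
                           nullptr, nullptr, nullptr);
  List out = List::create(
    _["transition"] = trans, _["emission"] = emis, _["initProb"] = initp,
    _["logLik"] = logLik, _["iterations"] = it, _["converged"] = converged);
  if (wantPosteriors) {
    NumericMatrix post(T, K);
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k)
        post(t, k) = gamma[static_cast<size_t>(t) * K + k];
    out["posteriors"] = post;
  }
  return out;
}

// [[Rcpp::export(name = ".hmm_posteriors_multi")]]
NumericMatrix hmm_posteriors_multi(IntegerVector symbols,
                                   NumericMatrix trans, NumericMatrix emis,
                                   NumericVector initProb) {
  const int K = trans.nrow();
  std::vector<int> sym(symbols.begin(), symbols.end());
  const int T = static_cast<int>(sym.size());
  std::vector<double> ll(static_cast<size_t>(T) * K);
  std::vector<double> gamma(static_cast<size_t>(T) * K);
  std::vector<int> ptr(T + 1, 0);
  std::vector<int> spk;
  NumericMatrix tr = clone(trans);
  NumericVector ip = clone(initProb);
  emissionLogLikMulti(sym, emis, ll);
  forwardBackward(ll, spk, ptr, tr, ip, gamma, false, nullptr, nullptr,
                  nullptr);
  NumericMatrix post(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      post(t, k) = gamma[static_cast<size_t>(t) * K + k];
  return post;
}

// Posterior marginals under frozen parameters (no learning), used when
// decoding perturbation segments with the HMM of the unperturbed run.
// [[Rcpp::export(name = ".hmm_posteriors")]]
NumericMatrix hmm_posteriors(IntegerVector spikeNeuron, IntegerVector binPtr,
                             int nNeurons, NumericMatrix trans,
                             NumericMatrix emis, NumericVector initProb) {
  const int K = trans.nrow();
  std::vector<int> spk(spikeNeuron.begin(), spikeNeuron.end());
  std::vector<int> ptr(binPtr.begin(), binPtr.end());
  const int T = static_cast<int>(ptr.size()) - 1;
  std::vector<double> ll(static_cast<size_t>(T) * K);
  std::vector<double> gamma(static_cast<size_t>(T) * K);
  NumericMatrix tr = clone(trans);
  NumericVector ip = clone(initProb);
  emissionLogLik(spk, ptr, emis, ll);
  forwardBackward(ll, spk, ptr, tr, ip, gamma, false, nullptr, nullptr,
                  nullptr);
  NumericMatrix post(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      post(t, k) = gamma[static_cast<size_t>(t) * K + k];
  return post;
}
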