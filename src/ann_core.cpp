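// Minimal multilayer perceptron (n inputs -> H sigmoid hidden -> 1 sigmoid
// output) with per-pattern backpropagation + momentum, early stopping on a
// validation partition, and the whole-matrix single-probe screening loop.
// The screening loop lives here because it retrains the net
// n_probes x n_loops x n_resamples times; an interpreted inner loop is not
// viable at array scale.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic, platform-independent PRNG (splitmix64). Screening seeds are
// derived from (master seed, probe id) so per-probe results do not depend on
// screening order.
// ---------------------------------------------------------------------------
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int below(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

static uint64_t fnv1a64(const std::string& s) {
  uint64_t h = 1469598103934665603ULL;
  for (size_t i = 0; i < s.size(); ++i) {
    h ^= static_cast<unsigned char>(s[i]);
    h *= 1099511628211ULL;
  }
  return h;
}

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// ---------------------------------------------------------------------------
// Network: weights flattened as wIn[h*I + i], bH[h], wO[h], bO.
// ---------------------------------------------------------------------------
struct Net {
  int I, H;
  std::vector<double> wIn, bH, wO;
  double bO;
  Net(int I_, int H_) : I(I_), H(H_), wIn(I_ * H_, 0.0), bH(H_, 0.0),
                        wO(H_, 0.0), bO(0.0) {}
};

static inline double net_forward(const Net& n, const double* x, double* act) {
  double z = n.bO;
  for (int h = 0; h < n.H; ++h) {
    double a = n.bH[h];
    for (int i = 0; i < n.I; ++i) a += n.wIn[h * n.I + i] * x[i];
    a = sigm(a);
    act[h] = a;
    z += n.wO[h] * a;
  }
  return sigm(z);
}

static double net_rms(const Net& n, const std::vector<double>& X,
                      const std::vector<double>& y) {
  int m = static_cast<int>(y.size());
  if (m == 0) return 0.0;
  std::vector<double> act(n.H);
  double ss = 0.0;
  for (int p = 0; p < m; ++p) {
    double o = net_forward(n, &X[p * n.I], act.data());
    double d = o - y[p];
    ss += d * d;
  }
  return std::sqrt(ss / m);
}

// One online (per-pattern, fixed order) epoch of backprop with momentum on
// squared error E = 0.5 (o - y)^2; velocities persist across epochs.
static void epoch_update(Net& n, const std::vector<double>& X,
                         const std::vector<double>& y,
                         double lr, double mom,
                         Net& vel) {
  int m = static_cast<int>(y.size());
  std::vector<double> act(n.H);
  for (int p = 0; p < m; ++p) {
    const double* x = &X[p * n.I];
    double o = net_forward(n, x, act.data());
    double dO = (o - y[p]) * o * (1.0 - o);
    // hidden deltas use pre-update output weights
    for (int h = 0; h < n.H; ++h) {
      double dH = dO * n.wO[h] * act[h] * (1.0 - act[h]);
      for (int i = 0; i < n.I; ++i) {
        double& v = vel.wIn[h * n.I + i];
        v = mom * v - lr * dH * x[i];
        n.wIn[h * n.I + i] += v;
      }
      double& vb = vel.bH[h];
      vb = mom * vb - lr * dH;
      n.bH[h] += vb;
    }
    for (int h = 0; h < n.H; ++h) {
      double& v = vel.wO[h];
      v = mom * v - lr * dO * act[h];
      n.wO[h] += v;
    }
    vel.bO = mom * vel.bO - lr * dO;
    n.bO += vel.bO;
  }
}

struct TrainOut {
  Net best, final;
  int bestEpoch;
  std::vector<double> trainRms, valRms;
  TrainOut(int I, int H) : best(I, H), final(I, H), bestEpoch(0) {}
};

// Early stopping: validation RMS evaluated after each epoch; training stops
// when it has not strictly improved for `patience` consecutive epochs (or at
// maxEpochs); the weights of the best validation epoch are returned.
static void train_core(Net net, const std::vector<double>& trX,
                       const std::vector<double>& trY,
                       const std::vector<double>& vaX,
                       const std::vector<double>& vaY,
                       double lr, double mom, int maxEpochs, int patience,
                       double minDelta, bool recordTrain, TrainOut& out) {
  Net vel(net.I, net.H);
  out.best = net;
  out.final = net;
  out.bestEpoch = 0;
  double bestVal = R_PosInf;     // strict minimum: selects returned weights
  double patienceRef = R_PosInf; // improvement must beat this by minDelta
  int since = 0;
  for (int e = 1; e <= maxEpochs; ++e) {
    epoch_update(net, trX, trY, lr, mom, vel);
    double v = net_rms(net, vaX, vaY);
    out.valRms.push_back(v);
    if (recordTrain) out.trainRms.push_back(net_rms(net, trX, trY));
    if (v < bestVal) {
      bestVal = v;
      out.best = net;
      out.bestEpoch = e;
    }
    if (v < patienceRef - minDelta) {
      patienceRef = v;
      since = 0;
    } else if (++since >= patience) {
      break;
    }
  }
  out.final = net;
}

static Net net_from_r(NumericMatrix wIn, NumericVector bH, NumericVector wO,
                      double bO) {
  int H = wIn.nrow(), I = wIn.ncol();
  Net n(I, H);
  for (int h = 0; h < H; ++h)
    for (int i = 0; i < I; ++i) n.wIn[h * I + i] = wIn(h, i);
  for (int h = 0; h < H; ++h) { n.bH[h] = bH[h]; n.wO[h] = wO[h]; }
  n.bO = bO;
  return n;
}

static List net_to_r(const Net& n) {
  NumericMatrix wIn(n.H, n.I);
  NumericVector bH(n.H), wO(n.H);
  for (int h = 0; h < n.H; ++h)
    for (int i = 0; i < n.I; ++i) wIn(h, i) = n.wIn[h * n.I + i];
  for (int h = 0; h < n.H; ++h) { bH[h] = n.bH[h]; wO[h] = n.wO[h]; }
  return List::create(_["wIn"] = wIn, _["bHidden"] = bH, _["wOut"] = wO,
                      _["bOut"] = n.bO);
}

// rows of an R pattern matrix (n x I) flattened pattern-major
static void flatten_rows(NumericMatrix X, std::vector<double>& out) {
  int n = X.nrow(), I = X.ncol();
  out.resize(static_cast<size_t>(n) * I);
  for (int p = 0; p < n; ++p)
    for (int i = 0; i < I; ++i) out[p * I + i] = X(p, i);
}

// [[Rcpp::export]]
List cpp_train(NumericMatrix trainX, NumericVector trainY,
               NumericMatrix valX, NumericVector valY,
               NumericMatrix wIn, NumericVector bH, NumericVector wO,
               double bO, double lr, double momentum, int maxEpochs,
               int patience, double minDelta) {
  Net net = net_from_r(wIn, bH, wO, bO);
  std::vector<double> trX, vaX;
  flatten_rows(trainX, trX);
  flatten_rows(valX, vaX);
  std::vector<double> trY(trainY.begin(), trainY.end());
  std::vector<double> vaY(valY.begin(), valY.end());
  TrainOut out(net.I, net.H);
  train_core(net, trX, trY, vaX, vaY, lr, momentum, maxEpochs, patience,
             minDelta, true, out);
  return List::create(
      _["best"] = net_to_r(out.best), _["final"] = net_to_r(out.final),
      _["best_epoch"] = out.bestEpoch,
      _["train_rms"] = NumericVector(out.trainRms.begin(), out.trainRms.end()),
      _["val_rms"] = NumericVector(out.valRms.begin(), out.valRms.end()));
}

// Gradient of E = 0.5 (o - y)^2 for a single pattern (backprop path; the
// finite-difference oracle in the test suite goes through the R forward pass).
// [[Rcpp::export]]
List cpp_gradient(NumericMatrix wIn, NumericVector bH, NumericVector wO,
                  double bO, NumericVector x, double y) {
  Net n = net_from_r(wIn, bH, wO, bO);
  std::vector<double> act(n.H);
  double o = net_forward(n, REAL(x), act.data());
  double dO = (o - y) * o * (1.0 - o);
  NumericMatrix gIn(n.H, n.I);
  NumericVector gbH(n.H), gwO(n.H);
  for (int h = 0; h < n.H; ++h) {
    double dH = dO * n.wO[h] * act[h] * (1.0 - act[h]);
    for (int i = 0; i < n.I; ++i) gIn(h, i) = dH * x[i];
    gbH[h] = dH;
    gwO[h] = dO * act[h];
  }
  return List::create(_["wIn"] = gIn, _["bHidden"] = gbH, _["wOut"] = gwO,
                      _["bOut"] = dO);
}

// ---------------------------------------------------------------------------
// Whole-matrix single-probe screening.
// X: probes x samples; y: raw target expression over the same samples.
//
// Randomisation design: the MCCV split of model m is shared by every
// candidate probe (common random numbers — candidate scores for the same
// model index are computed on identical partitions, so ranking differences
// reflect the candidates, not split luck), while weight initialisation and
// bootstrap draws run on a per-probe substream hashed from
// (master seed, probe id). Both streams are independent of candidate order.
//
// Returns per-model test RMS and training classification accuracy for every
// probe, plus a degenerate-input flag (constant candidate/target on some
// fitting partition).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_screen(NumericMatrix X, NumericVector y, CharacterVector probeIds,
                int nLoops, int nResamples, double fTest, double fVal,
                int nHidden, double lr, double momentum, int maxEpochs,
                int patience, double minDelta, double initRange,
                bool scaleAll, bool bootstrap, double masterSeed) {
  const int nProbes = X.nrow();
  const int n = X.ncol();
  const int nModels = nLoops * nResamples;
  const int nTest = static_cast<int>(std::floor(fTest * n + 0.5));
  const int nVal = static_cast<int>(std::floor(fVal * n + 0.5));
  const int nTrain = n - nTest - nVal;
  if (nTrain < 1 || nTest < 1 || nVal < 1)
    stop("MCCV partition empty: n=%d gives train=%d/test=%d/val=%d", n,
         nTrain, nTest, nVal);

  NumericMatrix rms(nProbes, nModels), acc(nProbes, nModels);
  LogicalVector degenerate(nProbes);

  SplitMix64 master(static_cast<uint64_t>(masterSeed));
  const uint64_t splitBase = master.next();
  const uint64_t probeBase = master.next();

  // shared per-model splits and scaled targets
  std::vector<std::vector<int> > idxM(nModels, std::vector<int>(n));
  std::vector<std::vector<double> > ysM(nModels, std::vector<double>(n));
  std::vector<double> thrM(nModels);      // training-median class threshold
  std::vector<bool> tConstM(nModels);
  {
    SplitMix64 splitChain(splitBase);
    for (int m = 0; m < nModels; ++m) {
      SplitMix64 ms(splitChain.next());
      std::vector<int>& idx = idxM[m];
      for (int i = 0; i < n; ++i) idx[i] = i;
      for (int i = n - 1; i > 0; --i)
        std::swap(idx[i], idx[ms.below(i + 1)]);
      double tmin = R_PosInf, tmax = R_NegInf;
      const int fitLim = scaleAll ? n : nTrain;
      for (int i = 0; i < fitLim; ++i) {
        const double tv = y[scaleAll ? i : idx[i]];
        if (tv < tmin) tmin = tv;
        if (tv > tmax) tmax = tv;
      }
      const bool tConst = !(tmax > tmin);
      tConstM[m] = tConst;
      const double tden = tConst ? 1.0 : (tmax - tmin);
      std::vector<double>& ys = ysM[m];
      for (int s = 0; s < n; ++s) {
        double t = tConst ? 0.5 : 0.1 + 0.8 * (y[s] - tmin) / tden;
        ys[s] = t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);           // -> [0.1,0.9]
      }
      std::vector<double> med(nTrain);
      for (int i = 0; i < nTrain; ++i) med[i] = ys[idx[i]];
      std::sort(med.begin(), med.end());
      thrM[m] = nTrain % 2 ? med[nTrain / 2]
                           : 0.5 * (med[nTrain / 2 - 1] + med[nTrain / 2]);
    }
  }

  std::vector<double> xs(n);
  std::vector<double> trX(nTrain), trY(nTrain), vaX(nVal), vaY(nVal);
  std::vector<double> a(nHidden);

  for (int p = 0; p < nProbes; ++p) {
    if (p % 64 == 0) Rcpp::checkUserInterrupt();
    const std::string pid = as<std::string>(probeIds[p]);
    SplitMix64 chain(probeBase ^ fnv1a64(pid));
    bool degen = false;

    for (int m = 0; m < nModels; ++m) {
      SplitMix64 ms(chain.next());
      const std::vector<int>& idx = idxM[m];
      const std::vector<double>& ys = ysM[m];
      if (tConstM[m]) degen = true;

      // candidate scaling fit on the training partition (or on all samples
      // with the fit-on-all compatibility switch)
      double xmin = R_PosInf, xmax = R_NegInf;
      const int fitLim = scaleAll ? n : nTrain;
      for (int i = 0; i < fitLim; ++i) {
        const double xv = X(p, scaleAll ? i : idx[i]);
        if (xv < xmin) xmin = xv;
        if (xv > xmax) xmax = xv;
      }
      const bool xConst = !(xmax > xmin);
      if (xConst) degen = true;
      const double xden = xConst ? 1.0 : (xmax - xmin);
      for (int s = 0; s < n; ++s)
        xs[s] = xConst ? 0.5 : (X(p, s) - xmin) / xden;        // -> [0,1]

      for (int i = 0; i < nTrain; ++i) {
        const int s = bootstrap ? idx[ms.below(nTrain)] : idx[i];
        trX[i] = xs[s];
        trY[i] = ys[s];
      }
      for (int i = 0; i < nVal; ++i) {
        const int s = idx[nTrain + i];
        vaX[i] = xs[s];
        vaY[i] = ys[s];
      }

      // weight init: uniform [-initRange, initRange]
      Net net(1, nHidden);
      for (int h = 0; h < nHidden; ++h)
        net.wIn[h] = (2.0 * ms.unif() - 1.0) * initRange;
      for (int h = 0; h < nHidden; ++h)
        net.bH[h] = (2.0 * ms.unif() - 1.0) * initRange;
      for (int h = 0; h < nHidden; ++h)
        net.wO[h] = (2.0 * ms.unif() - 1.0) * initRange;
      net.bO = (2.0 * ms.unif() - 1.0) * initRange;

      TrainOut out(1, nHidden);
      train_core(net, trX, trY, vaX, vaY, lr, momentum, maxEpochs, patience,
                 minDelta, false, out);
      const Net& fit = out.best;

      // test RMS on the held-out partition
      double ss = 0.0;
      for (int i = 0; i < nTest; ++i) {
        const int s = idx[nTrain + nVal + i];
        double o = net_forward(fit, &xs[s], a.data());
        double d = o - ys[s];
        ss += d * d;
      }
      rms(p, m) = std::sqrt(ss / nTest);

      // training classification accuracy against the target dichotomized at
      // the training-partition median (secondary metric)
      const double thr = thrM[m];
      int ok = 0;
      for (int i = 0; i < nTrain; ++i) {
        double o = net_forward(fit, &trX[i], a.data());
        if ((o >= thr) == (trY[i] >= thr)) ++ok;
      }
      acc(p, m) = 100.0 * ok / nTrain;
    }
    degenerate[p] = degen;
  }

  return List::create(_["rms"] = rms, _["acc"] = acc,
                      _["degenerate"] = degenerate,
                      _["sizes"] = IntegerVector::create(nTrain, nTest, nVal));
}

// 64-bit FNV-1a of a string, reduced to a hex string (config fingerprints).
// [[Rcpp::export]]
String cpp_hash_string(std::string s) {
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx",
           static_cast<unsigned long long>(fnv1a64(s)));
  return String(buf);
}
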