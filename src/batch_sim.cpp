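#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Activation codes: 0 linear, 1 relu, 2 satrelu, 3 satlin.
static inline double act(double z, int kind) {
  switch (kind) {
  case 1: return z > 0.0 ? z : 0.0;
  case 2: return z < 0.0 ? 0.0 : (z > 1.0 ? 1.0 : z);
  case 3: return z < -1.0 ? -1.0 : (z > 1.0 ? 1.0 : z);
  default: return z;
  }
}

// Batch simulation of hierarchical x/y networks plus per-level extraction of
// the traveling-wave criterion components. One row of W per model, 12
// columns in the package's connection-slot order:
//   1 xx_rec 2 xy_rec 3 yx_rec 4 yy_rec | 5..8 ff | 9..12 fb (src/dst x,y).
// The external input acts as a virtual level 0 whose x role (and y role if
// yIn != 0) equals the input value.
//
// Returns a list of nModels x nLevels matrices with, per observable unit:
// tM, M, tm, m (first-attained extrema, 0-based sample indices), logical
// criterion components (monotone rise, monotone tail, non-increasing and
// strictly decreasing decay), the half-life th (-1 when no half crossing),
// and a per-model `unstable` flag.
// [[Rcpp::export(name = ".batchSimComponents")]]
List batchSimComponents(NumericMatrix W, int actX, int actY, int nLevels,
                        int nSamples, int onStart, int onEnd,
                        double amplitude, int yIn, double tol) {
  const int M = W.nrow();
  const int L = nLevels;
  const int nT = nSamples;

  IntegerMatrix tM(M, L), tMl(M, L), tm(M, L), th(M, L), thL(M, L);
  NumericMatrix Mv(M, L), mv(M, L);
  LogicalMatrix riseOK(M, L), tailOK(M, L), decNI(M, L), decST(M, L);
  LogicalMatrix tailZeroOK(M, L), noOverOK(M, L);
  LogicalMatrix decNIL(M, L), decSTL(M, L);
  LogicalVector unstable(M);

  std::vector<double> x(L), y(L), nx(L), ny(L);
  std::vector<double> tr((size_t)L * nT);

  for (int mdl = 0; mdl < M; ++mdl) {
    // edge list of the model's nonzero connections: work scales with the
    // number of present connections, not with all 12 slots
    int nE = 0;
    int eSrc[12], eDst[12], eOff[12];
    double eW[12];
    for (int sl = 0; sl < 12; ++sl) {
      double w = W(mdl, sl);
      if (w == 0.0) continue;
      eSrc[nE] = (sl % 4) / 2;            // 0 = x source, 1 = y source
      eDst[nE] = sl % 2;                  // 0 = x target, 1 = y target
      eOff[nE] = (sl / 4 == 0) ? 0 : (sl / 4 == 1 ? 1 : -1);
      eW[nE] = w;
      ++nE;
    }
    std::fill(x.begin(), x.end(), 0.0);
    std::fill(y.begin(), y.end(), 0.0);
    for (int l = 0; l < L; ++l) tr[(size_t)l * nT] = 0.0;
    bool bad = false;

    for (int t = 1; t < nT && !bad; ++t) {
      double u = (t - 1 >= onStart && t - 1 < onEnd) ? amplitude : 0.0;
      std::fill(nx.begin(), nx.end(), 0.0);
      std::fill(ny.begin(), ny.end(), 0.0);
      for (int e = 0; e < nE; ++e) {
        const double w = eW[e];
        const double *src = eSrc[e] ? y.data() : x.data();
        double *dst = eDst[e] ? ny.data() : nx.data();
        if (eOff[e] == 0) {
          for (int l = 0; l < L; ++l) dst[l] += w * src[l];
        } else if (eOff[e] == 1) {
          dst[0] += w * ((eSrc[e] == 0 || yIn) ? u : 0.0);
          for (int l = 1; l < L; ++l) dst[l] += w * src[l - 1];
        } else {
          for (int l = 0; l < L - 1; ++l) dst[l] += w * src[l + 1];
        }
      }
      double mx = 0.0;
      for (int l = 0; l < L; ++l) {
        x[l] = act(nx[l], actX);
        y[l] = act(ny[l], actY);
        tr[(size_t)l * nT + t] = x[l];
        double ax_ = std::fabs(x[l]), ay_ = std::fabs(y[l]);
        if (ax_ > mx) mx = ax_;
        if (ay_ > mx) mx = ay_;
      }
      if (!(mx <= 1e6)) bad = true;       // catches NaN and overflow
    }
    unstable[mdl] = bad;
    if (bad) {
      for (int l = 0; l < L; ++l) { th(mdl, l) = -1; thL(mdl, l) = -1; }
      continue;
    }

    for (int l = 0; l < L; ++l) {
      const double *v = &tr[(size_t)l * nT];
      int iMax = 0, iMin = 0, iMaxL = 0;
      for (int t = 1; t < nT; ++t) {
        if (v[t] > v[iMax]) iMax = t;
        if (v[t] < v[iMin]) iMin = t;
      }
      for (int t = nT - 1; t >= 0; --t)
        if (v[t] == v[iMax]) { iMaxL = t; break; }
      tM(mdl, l) = iMax;
      tMl(mdl, l) = iMaxL;
      tm(mdl, l) = iMin;
      Mv(mdl, l) = v[iMax];
      mv(mdl, l) = v[iMin];

      bool rise = true;
      for (int t = onStart + 1; t <= iMax; ++t)
        if (v[t] - v[t - 1] < -tol) { rise = false; break; }
      riseOK(mdl, l) = rise;

      bool tail = true;
      for (int t = iMin + 1; t < nT; ++t)
        if (v[t] - v[t - 1] < -tol) { tail = false; break; }
      tailOK(mdl, l) = tail;

      // monotone recovery only up to the first return to (near) zero
      bool tz = true;
      for (int t = iMin + 1; t < nT && v[t - 1] < -tol; ++t)
        if (v[t] - v[t - 1] < -tol) { tz = false; break; }
      tailZeroOK(mdl, l) = tz;

      // no positive rebound after the offset minimum
      bool nov = true;
      for (int t = iMin + 1; t < nT; ++t)
        if (v[t] > tol) { nov = false; break; }
      noOverOK(mdl, l) = nov;

      bool ni = true, st = true;
      if (iMin > iMax) {
        for (int t = iMax + 1; t <= iMin; ++t) {
          double d = v[t] - v[t - 1];
          if (d > tol) { ni = false; st = false; break; }
          if (d >= 0.0) st = false;
        }
      } else {
        ni = false;
        st = false;
      }
      decNI(mdl, l) = ni;
      decST(mdl, l) = st;

      // same checks measured from the last attainment of the maximum
      bool niL = true, stL = true;
      if (iMin > iMaxL) {
        for (int t = iMaxL + 1; t <= iMin; ++t) {
          double d = v[t] - v[t - 1];
          if (d > tol) { niL = false; stL = false; break; }
          if (d >= 0.0) stL = false;
        }
      } else {
        niL = false;
        stL = false;
      }
      decNIL(mdl, l) = niL;
      decSTL(mdl, l) = stL;

      int cross = -1;
      for (int t = iMax; t < nT; ++t)
        if (v[t] <= Mv(mdl, l) / 2.0) { cross = t; break; }
      th(mdl, l) = (cross >= 0) ? cross - iMax : -1;
      int crossL = -1;
      for (int t = iMaxL; t < nT; ++t)
        if (v[t] <= Mv(mdl, l) / 2.0) { crossL = t; break; }
      thL(mdl, l) = (crossL >= 0) ? crossL - iMaxL : -1;
    }
  }

  return List::create(
    _["tM"] = tM, _["tMl"] = tMl, _["tm"] = tm, _["M"] = Mv, _["m"] = mv,
    _["decayNonIncL"] = decNIL, _["decayStrictL"] = decSTL, _["halfLifeL"] = thL,
    _["riseOK"] = riseOK, _["tailOK"] = tailOK,
    _["tailZeroOK"] = tailZeroOK, _["noOverOK"] = noOverOK,
    _["decayNonInc"] = decNI, _["decayStrict"] = decST,
    _["halfLife"] = th, _["unstable"] = unstable);
}
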