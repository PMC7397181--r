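#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Partition function over nested RNA secondary structures with a uniform
// per-pair Boltzmann weight w (Watson-Crick + GU wobble, minimum hairpin
// loop minH). Every structure's weight is w^(#pairs); the grammar
//   S(i,j) = S(i+1,j) | sum_k [ i~k ] w * S(i+1,k-1) * S(k+1,j)
// is unambiguous, so inside/outside sums count each structure once.
// Doubles overflow for long sequences, so inside values are rescaled by
// s^(segment length) with s chosen adaptively near the per-base growth rate.

static inline bool canPair(int a, int b) {
  // codes: 0=A 1=C 2=G 3=U
  int x = a * 4 + b;
  return x == 3 || x == 12 ||  // AU UA
         x == 6 || x == 9  ||  // CG GC
         x == 11 || x == 14;   // GU UG
}

struct Grid {
  int n;
  std::vector<double> v;
  Grid(int n_) : n(n_), v((size_t)(n_ + 2) * (n_ + 2), 0.0) {}
  // segment [i, j], 1-based; empty segment (j == i - 1) handled by caller
  double& at(int i, int j) { return v[(size_t)i * (n + 2) + j]; }
};

// partner lists: for each i (1-based), ascending positions k >= i+minH+1
// that can pair with i
static std::vector<std::vector<int> > partnerLists(const std::vector<int>& c,
                                                   int n, int minH) {
  std::vector<std::vector<int> > out(n + 1);
  for (int i = 1; i <= n; ++i)
    for (int k = i + minH + 1; k <= n; ++k)
      if (canPair(c[i - 1], c[k - 1])) out[i].push_back(k);
  return out;
}

// inside fill; returns false on overflow/non-finite. Z.at(i,j) holds
// Z(i,j)/s^(j-i+1); empty segments are implicitly 1. ZT is the transpose
// (ZT.at(j,i) == Z.at(i,j)), kept so the Z(k+1,j) factor is read with
// unit stride in k.
static bool insideFill(const std::vector<int>& c, int n, double w, double s,
                       int minH, Grid& Z, Grid& ZT,
                       const std::vector<std::vector<int> >& partners) {
  const double invS = 1.0 / s;
  const double wss = w / (s * s);
  for (int len = 1; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      double val = (i + 1 > j ? 1.0 : Z.at(i + 1, j)) * invS;
      const std::vector<int>& pl = partners[i];
      const double* rowL = &Z.v[(size_t)(i + 1) * (Z.n + 2)];
      const double* rowR = &ZT.v[(size_t)j * (Z.n + 2)];
      for (size_t t = 0; t < pl.size(); ++t) {
        int k = pl[t];
        if (k > j) break;
        double right = (k == j) ? 1.0 : rowR[k + 1];
        val += wss * rowL[k - 1] * right;
      }
      if (!std::isfinite(val)) return false;
      Z.at(i, j) = val;
      ZT.at(j, i) = val;
    }
  }
  return true;
}

// pick a scale so the scaled full partition function stays representable
static double chooseScale(const std::vector<int>& c, int n, double w, int minH) {
  int m = std::min(n, 120);
  std::vector<int> pre(c.begin(), c.begin() + m);
  std::vector<std::vector<int> > partners = partnerLists(pre, m, minH);
  double s = 1.0;
  for (int it = 0; it < 20; ++it) {
    Grid Z(m), ZT(m);
    bool ok = insideFill(pre, m, w, s, minH, Z, ZT, partners);
    double z = ok ? Z.at(1, m) : R_PosInf;
    if (ok && z > 1e-200 && z < 1e200)
      return s * std::pow(z, 1.0 / m);
    s *= ok ? 0.25 : 4.0;
  }
  return s;
}

static bool runInside(const std::vector<int>& c, int n, double w, int minH,
                      Grid& Z, Grid& ZT,
                      const std::vector<std::vector<int> >& partners,
                      double& scale) {
  double s = chooseScale(c, n, w, minH);
  for (int it = 0; it < 30; ++it) {
    std::fill(Z.v.begin(), Z.v.end(), 0.0);
    std::fill(ZT.v.begin(), ZT.v.end(), 0.0);
    bool ok = insideFill(c, n, w, s, minH, Z, ZT, partners);
    double z = ok ? Z.at(1, n) : R_PosInf;
    if (ok && z > 1e-120 && z < 1e120) { scale = s; return true; }
    if (!ok || !std::isfinite(z) || z >= 1e120) {
      s *= ok ? std::min(std::pow(z, 1.0 / n), 4.0) : 2.0;
    } else if (z <= 1e-120) {
      double f = std::pow(z, 1.0 / n); // < 1
      s *= std::max(f, 0.25);
    }
  }
  return false;
}

static std::vector<int> checkCodes(const IntegerVector& codes) {
  std::vector<int> c(codes.size());
  for (int i = 0; i < codes.size(); ++i) {
    if (codes[i] < 0 || codes[i] > 3) stop("sequence codes must be in 0..3");
    c[i] = codes[i];
  }
  return c;
}

// [[Rcpp::export(name = ".pairProbMatrixCpp")]]
NumericMatrix pairProbMatrixCpp(IntegerVector codes, double pairWeight,
                                int minHairpin) {
  std::vector<int> c = checkCodes(codes);
  int n = c.size();
  NumericMatrix P(n, n);
  if (n < minHairpin + 2) return P;
  std::vector<std::vector<int> > partners = partnerLists(c, n, minHairpin);
  Grid Z(n), ZT(n);
  double s = 1.0;
  if (!runInside(c, n, pairWeight, minHairpin, Z, ZT, partners, s))
    stop("partition function could not be rescaled into double range");
  const double invS = 1.0 / s;
  const double wss = pairWeight / (s * s);
  // outside: ZO.at(i,j) = ZO(i,j) / s^(n - (j-i+1))
  Grid ZO(n);
  ZO.at(1, n) = 1.0;
  for (int len = n; len >= 2; --len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      double zo = ZO.at(i, j);
      if (zo == 0.0) continue;
      ZO.at(i + 1, j) += zo * invS;
      for (int k = i + minHairpin + 1; k <= j; ++k) {
        if (!canPair(c[i - 1], c[k - 1])) continue;
        double right = (k + 1 > j) ? 1.0 : Z.at(k + 1, j);
        ZO.at(i + 1, k - 1) += zo * wss * right;
        if (k + 1 <= j) ZO.at(k + 1, j) += zo * wss * Z.at(i + 1, k - 1);
      }
    }
  }
  double Zfull = Z.at(1, n);
  for (int i = 1; i <= n; ++i) {
    for (int k = i + minHairpin + 1; k <= n; ++k) {
      if (!canPair(c[i - 1], c[k - 1])) continue;
      double ob = 0.0;
      for (int j = k; j <= n; ++j) {
        double right = (k + 1 > j) ? 1.0 : Z.at(k + 1, j);
        ob += ZO.at(i, j) * right;
      }
      double p = wss * Z.at(i + 1, k - 1) * ob / Zfull;
      if (p < 0) p = 0;
      if (p > 1) p = 1;
      P(i - 1, k - 1) = p;
      P(k - 1, i - 1) = p;
    }
  }
  return P;
}

// mean per-base pairedness = 2 E[#pairs] / n, with E[#pairs] = w dlogZ/dw,
// computed in one inside pass carrying (value, d/dw) pairs.
// [[Rcpp::export(name = ".meanPairednessCpp")]]
double meanPairednessCpp(IntegerVector codes, double pairWeight,
                         int minHairpin) {
  std::vector<int> c = checkCodes(codes);
  int n = c.size();
  if (n < minHairpin + 2) return 0.0;
  std::vector<std::vector<int> > partners = partnerLists(c, n, minHairpin);
  Grid Zpre(n), ZTpre(n);
  double s = 1.0;
  if (!runInside(c, n, pairWeight, minHairpin, Zpre, ZTpre, partners, s))
    stop("partition function could not be rescaled into double range");
  Grid Z(n), ZT(n), D(n), DT(n);
  const double invS = 1.0 / s;
  const double wss = pairWeight / (s * s);
  const double dwss = 1.0 / (s * s);
  for (int len = 1; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      double val = (i + 1 > j ? 1.0 : Z.at(i + 1, j)) * invS;
      double dvl = (i + 1 > j ? 0.0 : D.at(i + 1, j)) * invS;
      const std::vector<int>& pl = partners[i];
      const double* rowL = &Z.v[(size_t)(i + 1) * (Z.n + 2)];
      const double* rowLD = &D.v[(size_t)(i + 1) * (D.n + 2)];
      const double* rowR = &ZT.v[(size_t)j * (ZT.n + 2)];
      const double* rowRD = &DT.v[(size_t)j * (DT.n + 2)];
      for (size_t t = 0; t < pl.size(); ++t) {
        int k = pl[t];
        if (k > j) break;
        double a = rowL[k - 1], da = rowLD[k - 1];
        double b = (k == j) ? 1.0 : rowR[k + 1];
        double db = (k == j) ? 0.0 : rowRD[k + 1];
        val += wss * a * b;
        dvl += dwss * a * b + wss * (da * b + a * db);
      }
      Z.at(i, j) = val;  ZT.at(j, i) = val;
      D.at(i, j) = dvl;  DT.at(j, i) = dvl;
    }
  }
  double epairs = pairWeight * D.at(1, n) / Z.at(1, n);
  double m = 2.0 * epairs / n;
  if (m < 0) m = 0;
  if (m > 1) m = 1;
  return m;
}
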