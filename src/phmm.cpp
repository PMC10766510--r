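// Profile HMM forward algorithm in log space, with gradients.
//
// State topology (m match states, begin M0, end M_{m+1}):
//   M_k -> { M_{k+1}, I_k, D_{k+1} }   (M_m -> D_{m+1} is masked out)
//   I_k -> { M_{k+1}, I_k }
//   D_k -> { M_{k+1}, D_{k+1} }        (D_m -> D_{m+1} is masked out)
// Insert states emit uniformly (1/4); M_{m+1} emits the end token with
// probability 1.  All arithmetic in log space; "zero" probabilities are a
// finite floor (-1e10) so gradients stay finite during training.
//
// Parameter layouts (column-major R arrays, one slab per sequence):
//   le  : (4, m, N)     log match emissions, le[c + 4*(k-1)]
//   ltM : (3, m+1, N)   log a_{M_k,.} over (M, I, D), k = 0..m
//   ltI : (2, m+1, N)   log a_{I_k,.} over (M, I),    k = 0..m
//   ltD : (2, m, N)     log a_{D_k,.} over (M, D),    k = 1..m
//
// Gradients are with respect to the log-parameters treated as free
// (i.e. posterior expected usage counts); the R side chains them through
// the softmax that produced the normalized distributions.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG_FLOOR = -1e10;
static const double FLOOR_GUARD = -1e9; // anything below this is "zero"
static const double LOG_QUARTER = -1.3862943611198906; // log(1/4)

static inline double lse2(double a, double b) {
  double m = a > b ? a : b;
  if (m < FLOOR_GUARD) return LOG_FLOOR;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}
static inline double lse3(double a, double b, double c) {
  double m = a > b ? a : b;
  if (c > m) m = c;
  if (m < FLOOR_GUARD) return LOG_FLOOR;
  return m + std::log(std::exp(a - m) + std::exp(b - m) + std::exp(c - m));
}

// Workspace for one sequence: lattices (m+1) x (L+1), rows k = 0..m.
struct Lattice {
  int m, L;
  std::vector<double> fM, fI, fD;
  Lattice(int m_, int L_) : m(m_), L(L_),
    fM((m_ + 1) * (L_ + 1), LOG_FLOOR),
    fI((m_ + 1) * (L_ + 1), LOG_FLOOR),
    fD((m_ + 1) * (L_ + 1), LOG_FLOOR) {}
  inline int at(int k, int l) const { return k + (m + 1) * l; }
};

// x: 1-based letters x[1..L] (values 0..3), x[0] unused.
static double forward_fill(int m, int L, const int* x,
                           const double* le, const double* ltM,
                           const double* ltI, const double* ltD,
                           Lattice& w) {
  std::fill(w.fM.begin(), w.fM.end(), LOG_FLOOR);
  std::fill(w.fI.begin(), w.fI.end(), LOG_FLOOR);
  std::fill(w.fD.begin(), w.fD.end(), LOG_FLOOR);
  w.fM[w.at(0, 0)] = 0.0;
  for (int l = 0; l <= L; ++l) {
    if (l > 0) {
      for (int k = 1; k <= m; ++k) {
        double t1 = ltM[0 + 3 * (k - 1)] + w.fM[w.at(k - 1, l - 1)];
        double t2 = ltI[0 + 2 * (k - 1)] + w.fI[w.at(k - 1, l - 1)];
        double t3 = (k >= 2) ? ltD[0 + 2 * (k - 2)] + w.fD[w.at(k - 1, l - 1)]
                             : LOG_FLOOR;
        double s = lse3(t1, t2, t3);
        double e = le[x[l] + 4 * (k - 1)];
        w.fM[w.at(k, l)] = (s < FLOOR_GUARD || e < FLOOR_GUARD) ? LOG_FLOOR
                                                                : e + s;
      }
      for (int k = 0; k <= m; ++k) {
        double t1 = ltM[1 + 3 * k] + w.fM[w.at(k, l - 1)];
        double t2 = ltI[1 + 2 * k] + w.fI[w.at(k, l - 1)];
        double s = lse2(t1, t2);
        w.fI[w.at(k, l)] = (s < FLOOR_GUARD) ? LOG_FLOOR : LOG_QUARTER + s;
      }
    }
    for (int k = 1; k <= m; ++k) {
      double t1 = ltM[2 + 3 * (k - 1)] + w.fM[w.at(k - 1, l)];
      double t2 = (k >= 2) ? ltD[1 + 2 * (k - 2)] + w.fD[w.at(k - 1, l)]
                           : LOG_FLOOR;
      w.fD[w.at(k, l)] = lse2(t1, t2);
    }
  }
  return lse3(ltM[0 + 3 * m] + w.fM[w.at(m, L)],
              ltI[0 + 2 * m] + w.fI[w.at(m, L)],
              ltD[0 + 2 * (m - 1)] + w.fD[w.at(m, L)]);
}

// Adjoint (reverse) sweep: accumulates d logp / d log-parameter.
static void adjoint_fill(int m, int L, const int* x,
                         const double* le, const double* ltM,
                         const double* ltI, const double* ltD,
                         const Lattice& w, double logp,
                         double* gle, double* gtM, double* gtI, double* gtD) {
  if (logp < FLOOR_GUARD) return; // zero-probability sequence: no signal
  std::vector<double> aM((m + 1) * (L + 1), 0.0), aI(aM), aD(aM);
  // termination: transition into M_{m+1} emitting the end token
  {
    double t, wgt;
    t = ltM[0 + 3 * m] + w.fM[w.at(m, L)];
    wgt = std::exp(t - logp);
    aM[w.at(m, L)] += wgt; gtM[0 + 3 * m] += wgt;
    t = ltI[0 + 2 * m] + w.fI[w.at(m, L)];
    wgt = std::exp(t - logp);
    aI[w.at(m, L)] += wgt; gtI[0 + 2 * m] += wgt;
    t = ltD[0 + 2 * (m - 1)] + w.fD[w.at(m, L)];
    wgt = std::exp(t - logp);
    aD[w.at(m, L)] += wgt; gtD[0 + 2 * (m - 1)] += wgt;
  }
  for (int l = L; l >= 0; --l) {
    // D cells first (they feed M cells of the same column), k descending
    for (int k = m; k >= 1; --k) {
      double a = aD[w.at(k, l)];
      double v = w.fD[w.at(k, l)];
      if (a == 0.0 || v < FLOOR_GUARD) continue;
      double t1 = ltM[2 + 3 * (k - 1)] + w.fM[w.at(k - 1, l)];
      double w1 = std::exp(t1 - v);
      aM[w.at(k - 1, l)] += a * w1; gtM[2 + 3 * (k - 1)] += a * w1;
      if (k >= 2) {
        double t2 = ltD[1 + 2 * (k - 2)] + w.fD[w.at(k - 1, l)];
        double w2 = std::exp(t2 - v);
        aD[w.at(k - 1, l)] += a * w2; gtD[1 + 2 * (k - 2)] += a * w2;
      }
    }
    if (l == 0) continue;
    for (int k = 1; k <= m; ++k) {
      double a = aM[w.at(k, l)];
      double fv = w.fM[w.at(k, l)];
      if (a == 0.0 || fv < FLOOR_GUARD) continue;
      gle[x[l] + 4 * (k - 1)] += a;
      double v = fv - le[x[l] + 4 * (k - 1)]; // the lse part
      double t1 = ltM[0 + 3 * (k - 1)] + w.fM[w.at(k - 1, l - 1)];
      double w1 = std::exp(t1 - v);
      aM[w.at(k - 1, l - 1)] += a * w1; gtM[0 + 3 * (k - 1)] += a * w1;
      double t2 = ltI[0 + 2 * (k - 1)] + w.fI[w.at(k - 1, l - 1)];
      double w2 = std::exp(t2 - v);
      aI[w.at(k - 1, l - 1)] += a * w2; gtI[0 + 2 * (k - 1)] += a * w2;
      if (k >= 2) {
        double t3 = ltD[0 + 2 * (k - 2)] + w.fD[w.at(k - 1, l - 1)];
        double w3 = std::exp(t3 - v);
        aD[w.at(k - 1, l - 1)] += a * w3; gtD[0 + 2 * (k - 2)] += a * w3;
      }
    }
    for (int k = 0; k <= m; ++k) {
      double a = aI[w.at(k, l)];
      double fv = w.fI[w.at(k, l)];
      if (a == 0.0 || fv < FLOOR_GUARD) continue;
      double v = fv - LOG_QUARTER;
      double t1 = ltM[1 + 3 * k] + w.fM[w.at(k, l - 1)];
      double w1 = std::exp(t1 - v);
      aM[w.at(k, l - 1)] += a * w1; gtM[1 + 3 * k] += a * w1;
      double t2 = ltI[1 + 2 * k] + w.fI[w.at(k, l - 1)];
      double w2 = std::exp(t2 - v);
      aI[w.at(k, l - 1)] += a * w2; gtI[1 + 2 * k] += a * w2;
    }
  }
}

// [[Rcpp::export]]
List phmm_forward_cpp(NumericVector le, NumericVector ltM, NumericVector ltI,
                      NumericVector ltD, IntegerMatrix seqs,
                      IntegerVector lens, bool grad) {
  IntegerVector dle = le.attr("dim");
  int m = dle[1];
  int N = dle[2];
  int Lmax = seqs.nrow();
  if (seqs.ncol() != N || lens.size() != N)
    stop("sequence batch does not match parameter batch");
  const double* ple = REAL(le);
  const double* ptM = REAL(ltM);
  const double* ptI = REAL(ltI);
  const double* ptD = REAL(ltD);
  int sle = 4 * m, stM = 3 * (m + 1), stI = 2 * (m + 1), stD = 2 * m;
  NumericVector logp(N);
  NumericVector gle, gtM, gtI, gtD;
  double *pgle = nullptr, *pgtM = nullptr, *pgtI = nullptr, *pgtD = nullptr;
  if (grad) {
    gle = NumericVector(sle * N); gle.attr("dim") = dle;
    gtM = NumericVector(stM * N); gtM.attr("dim") = ltM.attr("dim");
    gtI = NumericVector(stI * N); gtI.attr("dim") = ltI.attr("dim");
    gtD = NumericVector(stD * N); gtD.attr("dim") = ltD.attr("dim");
    pgle = REAL(gle); pgtM = REAL(gtM); pgtI = REAL(gtI); pgtD = REAL(gtD);
  }
  Lattice w(m, Lmax);
  std::vector<int> x(Lmax + 1);
  for (int n = 0; n < N; ++n) {
    int L = lens[n];
    if (L > Lmax) stop("sequence length exceeds batch matrix");
    for (int l = 1; l <= L; ++l) {
      int c = seqs(l - 1, n);
      if (c < 1 || c > 4) stop("invalid letter code at sequence %d", n + 1);
      x[l] = c - 1;
    }
    Lattice wl(m, L);
    double lp = forward_fill(m, L, x.data(), ple + sle * n, ptM + stM * n,
                             ptI + stI * n, ptD + stD * n, wl);
    logp[n] = lp;
    if (grad)
      adjoint_fill(m, L, x.data(), ple + sle * n, ptM + stM * n,
                   ptI + stI * n, ptD + stD * n, wl, lp,
                   pgle + sle * n, pgtM + stM * n, pgtI + stI * n,
                   pgtD + stD * n);
  }
  if (grad)
    return List::create(_["logp"] = logp, _["gle"] = gle, _["gtM"] = gtM,
                        _["gtI"] = gtI, _["gtD"] = gtD);
  return List::create(_["logp"] = logp);
}

// Full lattice for one sequence (diagnostics / tests).
// [[Rcpp::export]]
List phmm_lattice_cpp(NumericVector le, NumericVector ltM, NumericVector ltI,
                      NumericVector ltD, IntegerVector seq) {
  IntegerVector dle = le.attr("dim");
  int m = dle[1];
  int L = seq.size();
  std::vector<int> x(L + 1);
  for (int l = 1; l <= L; ++l) x[l] = seq[l - 1] - 1;
  Lattice w(m, L);
  double lp = forward_fill(m, L, x.data(), REAL(le), REAL(ltM), REAL(ltI),
                           REAL(ltD), w);
  NumericMatrix fM(m + 1, L + 1), fI(m + 1, L + 1), fD(m + 1, L + 1);
  for (int l = 0; l <= L; ++l)
    for (int k = 0; k <= m; ++k) {
      fM(k, l) = w.fM[w.at(k, l)];
      fI(k, l) = w.fI[w.at(k, l)];
      fD(k, l) = w.fD[w.at(k, l)];
    }
  return List::create(_["logp"] = lp, _["fM"] = fM, _["fI"] = fI,
                      _["fD"] = fD);
}
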