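// 1-D convolution stack with layer normalization, ReLU and additive skip
// connections.
//
// Activations are (N*L) x C matrices, position-major / sequence-minor
// (row (l-1)*N + n is position l of sequence n), so the K kernel taps are
// GEMMs against row-shifted views. Each block is
//   Z = conv_K(M);  Y = LN(Z) * gamma + beta;  M = relu(Y) + M
// with layer normalization over channels per position (deterministic per
// sample, no running statistics). Forward caches layer inputs, normalized
// activations, inverse standard deviations and ReLU masks for the exact
// backward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LN_EPS = 1e-5;

// W: (K*C x C x nlayers), G,B: (C x nlayers), M0: (NL x C)
// [[Rcpp::export]]
List conv_stack_fwd_cpp(const arma::mat& M0, const arma::cube& W,
                        const arma::mat& G, const arma::mat& B,
                        int N, int K, bool cache) {
  int NL = M0.n_rows, C = M0.n_cols, nlay = W.n_slices;
  int h = (K - 1) / 2;
  arma::mat M = M0;
  arma::cube Ms, XH, masks;
  arma::mat ISD;
  if (cache) {
    Ms.set_size(NL, C, nlay + 1);
    XH.set_size(NL, C, nlay);
    masks.set_size(NL, C, nlay);
    ISD.set_size(NL, nlay);
    Ms.slice(0) = M0;
  }
  for (int i = 0; i < nlay; ++i) {
    const arma::mat& Wi = W.slice(i);
    arma::mat Z(NL, C, arma::fill::zeros);
    for (int t = 0; t < K; ++t) {
      int o = t - h, s = std::abs(o) * N;
      arma::mat Wt = Wi.rows(t * C, (t + 1) * C - 1);
      if (o == 0) Z += M * Wt;
      else if (s < NL) {
        if (o < 0) Z.rows(s, NL - 1) += M.rows(0, NL - s - 1) * Wt;
        else Z.rows(0, NL - s - 1) += M.rows(s, NL - 1) * Wt;
      }
    }
    arma::vec mu = arma::mean(Z, 1);
    arma::vec v = arma::mean(arma::square(Z), 1) - arma::square(mu);
    arma::vec isd = 1.0 / arma::sqrt(v + LN_EPS);
    arma::mat xh = Z.each_col() - mu;
    xh.each_col() %= isd;
    arma::mat Y = xh;
    Y.each_row() %= G.col(i).t();
    Y.each_row() += B.col(i).t();
    arma::mat mask = arma::conv_to<arma::mat>::from(Y > 0);
    M += Y % mask;
    if (cache) {
      Ms.slice(i + 1) = M; XH.slice(i) = xh; masks.slice(i) = mask;
      ISD.col(i) = isd;
    }
  }
  if (cache)
    return List::create(_["M"] = M, _["Ms"] = Ms, _["XH"] = XH,
                        _["masks"] = masks, _["ISD"] = ISD);
  return List::create(_["M"] = M);
}

// [[Rcpp::export]]
List conv_stack_bwd_cpp(const arma::mat& dMtop, const arma::cube& Ms,
                        const arma::cube& XH, const arma::cube& masks,
                        const arma::mat& ISD, const arma::cube& W,
                        const arma::mat& G, int N, int K) {
  int NL = dMtop.n_rows, C = dMtop.n_cols, nlay = W.n_slices;
  int h = (K - 1) / 2;
  arma::mat dM = dMtop;
  arma::cube gW(K * C, C, nlay, arma::fill::zeros);
  arma::mat gG(C, nlay, arma::fill::zeros), gB(C, nlay, arma::fill::zeros);
  for (int i = nlay - 1; i >= 0; --i) {
    const arma::mat& Wi = W.slice(i);
    const arma::mat& xh = XH.slice(i);
    arma::mat dY = dM % masks.slice(i);
    gG.col(i) = arma::sum(dY % xh, 0).t();
    gB.col(i) = arma::sum(dY, 0).t();
    arma::mat dxh = dY.each_row() % G.col(i).t();
    arma::vec m1 = arma::mean(dxh, 1);
    arma::vec m2 = arma::mean(dxh % xh, 1);
    arma::mat dZ = dxh;
    dZ.each_col() -= m1;
    dZ -= xh.each_col() % m2;
    dZ.each_col() %= ISD.col(i);
    const arma::mat& Min = Ms.slice(i);
    for (int t = 0; t < K; ++t) {
      int o = t - h, s = std::abs(o) * N;
      arma::mat Wt = Wi.rows(t * C, (t + 1) * C - 1);
      if (o == 0) {
        gW.slice(i).rows(t * C, (t + 1) * C - 1) = Min.t() * dZ;
        dM += dZ * Wt.t();
      } else if (s < NL) {
        if (o < 0) {
          gW.slice(i).rows(t * C, (t + 1) * C - 1) =
            Min.rows(0, NL - s - 1).t() * dZ.rows(s, NL - 1);
          dM.rows(0, NL - s - 1) += dZ.rows(s, NL - 1) * Wt.t();
        } else {
          gW.slice(i).rows(t * C, (t + 1) * C - 1) =
            Min.rows(s, NL - 1).t() * dZ.rows(0, NL - s - 1);
          dM.rows(s, NL - 1) += dZ.rows(0, NL - s - 1) * Wt.t();
        }
      }
    }
  }
  return List::create(_["dM"] = dM, _["gW"] = gW, _["gG"] = gG,
                      _["gB"] = gB);
}
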