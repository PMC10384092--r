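// Batched slice-wise scaled dot-product attention.
//
// Both attention variants in the package reduce to independent matrix
// attentions over the slices of a cube: multi-head attention over
// (time x head-width) slices, one per (head, batch) pair, and
// multi-channel attention over (H x W) feature maps, one per
// (channel, batch) pair. The R layers reshape to cubes and call these
// kernels; the softmax normalises each row (query) over the key axis.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void softmax_rows_inplace(mat& S) {
  for (uword i = 0; i < S.n_rows; ++i) {
    double m = S.row(i).max();
    rowvec e = exp(S.row(i) - m);
    S.row(i) = e / accu(e);
  }
}

// [[Rcpp::export]]
Rcpp::List attn_cube_fw(const Rcpp::NumericVector& Q,
                        const Rcpp::NumericVector& K,
                        const Rcpp::NumericVector& V,
                        int nq, int dk, int nk, int dv, int S,
                        double scale) {
  Rcpp::NumericVector out((long)nq * dv * S);
  Rcpp::NumericVector P((long)nq * nk * S);
  for (int s = 0; s < S; ++s) {
    const arma::mat Qs(const_cast<double*>(Q.begin()) + (long)s * nq * dk,
                       nq, dk, false, true);
    const arma::mat Ks(const_cast<double*>(K.begin()) + (long)s * nk * dk,
                       nk, dk, false, true);
    const arma::mat Vs(const_cast<double*>(V.begin()) + (long)s * nk * dv,
                       nk, dv, false, true);
    arma::mat Ps(P.begin() + (long)s * nq * nk, nq, nk, false, true);
    arma::mat Os(out.begin() + (long)s * nq * dv, nq, dv, false, true);
    Ps = Qs * Ks.t() * scale;
    softmax_rows_inplace(Ps);
    Os = Ps * Vs;
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("P") = P);
}

// [[Rcpp::export]]
Rcpp::List attn_cube_bw(const Rcpp::NumericVector& dout,
                        const Rcpp::NumericVector& P,
                        const Rcpp::NumericVector& Q,
                        const Rcpp::NumericVector& K,
                        const Rcpp::NumericVector& V,
                        int nq, int dk, int nk, int dv, int S,
                        double scale) {
  Rcpp::NumericVector dQ((long)nq * dk * S);
  Rcpp::NumericVector dK((long)nk * dk * S);
  Rcpp::NumericVector dV((long)nk * dv * S);
  for (int s = 0; s < S; ++s) {
    const arma::mat Qs(const_cast<double*>(Q.begin()) + (long)s * nq * dk,
                       nq, dk, false, true);
    const arma::mat Ks(const_cast<double*>(K.begin()) + (long)s * nk * dk,
                       nk, dk, false, true);
    const arma::mat Vs(const_cast<double*>(V.begin()) + (long)s * nk * dv,
                       nk, dv, false, true);
    const arma::mat Ps(const_cast<double*>(P.begin()) + (long)s * nq * nk,
                       nq, nk, false, true);
    const arma::mat dOs(const_cast<double*>(dout.begin()) +
                        (long)s * nq * dv, nq, dv, false, true);
    arma::mat dQs(dQ.begin() + (long)s * nq * dk, nq, dk, false, true);
    arma::mat dKs(dK.begin() + (long)s * nk * dk, nk, dk, false, true);
    arma::mat dVs(dV.begin() + (long)s * nk * dv, nk, dv, false, true);
    dVs = Ps.t() * dOs;
    arma::mat dP = dOs * Vs.t();
    arma::vec rs = arma::sum(dP % Ps, 1);
    dP.each_col() -= rs;
    dP %= Ps;
    dQs = dP * Ks * scale;
    dKs = dP.t() * Qs * scale;
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ,
                            Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}

// ---------------------------------------------------------------------------
// 2-D convolution (stride 1, square kernel) on (C, H, W, B) arrays.
// Weight rows index output channels; columns run over (input channel
// fastest, then row offset, then column offset), matching the R-side
// im2col layout. Backward rebuilds the im2col buffer from the cached
// layer input instead of caching it, trading a little compute for memory.

static void im2col2d(const double* x, int C, int H, int W, int b,
                     int k, int pad, arma::mat& Xcol) {
  const long plane = (long)C * H * W;
  const double* xb = x + (long)b * plane;
  Xcol.zeros();
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di) {
      const int rowoff = C * (di + k * dj);
      for (int j = 0; j < W; ++j) {
        const int jj = j + dj - pad;
        if (jj < 0 || jj >= W) continue;
        for (int i = 0; i < H; ++i) {
          const int ii = i + di - pad;
          if (ii < 0 || ii >= H) continue;
          std::memcpy(Xcol.colptr(i + (long)H * j) + rowoff,
                      xb + (long)C * (ii + (long)H * jj),
                      C * sizeof(double));
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector conv2d_fw_cpp(const Rcpp::NumericVector& x,
                                  const arma::mat& Wm,
                                  const arma::vec& bias,
                                  int C, int H, int W, int B,
                                  int k, int pad) {
  const int c_out = Wm.n_rows;
  Rcpp::NumericVector out((long)c_out * H * W * B);
  arma::mat Xcol(C * k * k, (long)H * W);
  for (int b = 0; b < B; ++b) {
    im2col2d(x.begin(), C, H, W, b, k, pad, Xcol);
    arma::mat y = Wm * Xcol;
    y.each_col() += bias;
    std::memcpy(out.begin() + (long)b * c_out * H * W, y.memptr(),
                sizeof(double) * y.n_elem);
  }
  out.attr("dim") = Rcpp::IntegerVector::create(c_out, H, W, B);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bw_cpp(const Rcpp::NumericVector& x,
                         const Rcpp::NumericVector& dy,
                         const arma::mat& Wm,
                         int C, int H, int W, int B,
                         int k, int pad) {
  const int c_out = Wm.n_rows;
  arma::mat dW(Wm.n_rows, Wm.n_cols, arma::fill::zeros);
  arma::vec db(c_out, arma::fill::zeros);
  Rcpp::NumericVector dx((long)C * H * W * B);
  arma::mat Xcol(C * k * k, (long)H * W);
  for (int b = 0; b < B; ++b) {
    im2col2d(x.begin(), C, H, W, b, k, pad, Xcol);
    const arma::mat dyb(const_cast<double*>(dy.begin()) +
                        (long)b * c_out * H * W,
                        c_out, (long)H * W, false, true);
    dW += dyb * Xcol.t();
    db += arma::sum(dyb, 1);
    arma::mat dXcol = Wm.t() * dyb;          // (C*k*k, H*W)
    double* dxb = dx.begin() + (long)b * C * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int rowoff = C * (di + k * dj);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + di - pad;
            if (ii < 0 || ii >= H) continue;
            const double* src = dXcol.colptr(i + (long)H * j) + rowoff;
            double* dst = dxb + (long)C * (ii + (long)H * jj);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  dx.attr("dim") = Rcpp::IntegerVector::create(C, H, W, B);
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dx") = dx);
}
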