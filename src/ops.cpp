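// Low-level numeric kernels for the CNN engine and trial preprocessing.
//
// Activation layout convention shared with the R side: a batch of N samples,
// each with S = H*W*D spatial positions and C channels, is stored as an
// (N*S) x C matrix whose rows are ordered sample-major, and within a sample
// by spatial index s = h + H*w + H*W*d (0-based, h fastest). Convolution
// kernels are flattened to K = kh*kw*kd taps, column index o + K*cin with
// o = ih + kh*iw + kh*kw*id.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// For each kernel offset (ih, iw, id) and input channel c, the column
// o + K*c of the im2col matrix is the input channel c shifted by the
// offset (zero padding outside). The shift moves whole h-runs, so rows are
// copied as contiguous segments.
static arma::mat im2col_one(const arma::mat& X, int H, int W, int D,
                            int kh, int kw, int kd) {
  const int S = H * W * D;
  const int Cin = X.n_cols;
  const int K = kh * kw * kd;
  const int rh = kh / 2, rw = kw / 2, rd = kd / 2;
  arma::mat col(S, (arma::uword)K * Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = X.colptr(c);
    for (int id = 0; id < kd; ++id) {
      const int dOff = id - rd;
      for (int iw = 0; iw < kw; ++iw) {
        const int wOff = iw - rw;
        for (int ih = 0; ih < kh; ++ih) {
          const int hOff = ih - rh;
          const int o = ih + kh * iw + kh * kw * id;
          double* cc = col.colptr(o + (arma::uword)K * c);
          const int h0 = std::max(0, -hOff), h1 = std::min(H, H - hOff);
          if (h0 >= h1) continue;
          for (int d = std::max(0, -dOff); d < std::min(D, D - dOff); ++d) {
            for (int w = std::max(0, -wOff); w < std::min(W, W - wOff); ++w) {
              const double* src = xc + (h0 + hOff) +
                (arma::uword)H * ((w + wOff) + (arma::uword)W * (d + dOff));
              double* dst = cc + h0 + (arma::uword)H * (w + (arma::uword)W * d);
              std::memcpy(dst, src, sizeof(double) * (h1 - h0));
            }
          }
        }
      }
    }
  }
  return col;
}

static void col2im_add(arma::mat& X, const arma::mat& col,
                       int H, int W, int D, int kh, int kw, int kd) {
  const int Cin = X.n_cols;
  const int K = kh * kw * kd;
  const int rh = kh / 2, rw = kw / 2, rd = kd / 2;
  for (int c = 0; c < Cin; ++c) {
    double* xc = X.colptr(c);
    for (int id = 0; id < kd; ++id) {
      const int dOff = id - rd;
      for (int iw = 0; iw < kw; ++iw) {
        const int wOff = iw - rw;
        for (int ih = 0; ih < kh; ++ih) {
          const int hOff = ih - rh;
          const int o = ih + kh * iw + kh * kw * id;
          const double* cc = col.colptr(o + (arma::uword)K * c);
          const int h0 = std::max(0, -hOff), h1 = std::min(H, H - hOff);
          if (h0 >= h1) continue;
          for (int d = std::max(0, -dOff); d < std::min(D, D - dOff); ++d) {
            for (int w = std::max(0, -wOff); w < std::min(W, W - wOff); ++w) {
              const double* src = cc + h0 +
                (arma::uword)H * (w + (arma::uword)W * d);
              double* dst = xc + (h0 + hOff) +
                (arma::uword)H * ((w + wOff) + (arma::uword)W * (d + dOff));
              for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cxConvFwd")]]
arma::mat cx_conv_fwd(const arma::mat& Xb, int n, int H, int W, int D,
                      int kh, int kw, int kd,
                      const arma::mat& Wmat, const arma::vec& bias) {
  const int S = H * W * D;
  const int Cout = Wmat.n_cols;
  arma::mat Y((arma::uword)n * S, Cout);
  for (int i = 0; i < n; ++i) {
    arma::mat col = im2col_one(Xb.rows((arma::uword)i * S, (arma::uword)(i + 1) * S - 1),
                               H, W, D, kh, kw, kd);
    arma::mat out = col * Wmat;
    out.each_row() += bias.t();
    Y.rows((arma::uword)i * S, (arma::uword)(i + 1) * S - 1) = out;
  }
  return Y;
}

// Gradients of a same-padded stride-1 convolution. Returns dX (if need_dx),
// dW and db accumulated over the batch.
// [[Rcpp::export(name = ".cxConvBwd")]]
List cx_conv_bwd(const arma::mat& Xb, const arma::mat& dY,
                 int n, int H, int W, int D, int kh, int kw, int kd,
                 const arma::mat& Wmat, bool need_dx) {
  const int S = H * W * D;
  const int Cin = Xb.n_cols;
  arma::mat dW(Wmat.n_rows, Wmat.n_cols, arma::fill::zeros);
  arma::vec db(Wmat.n_cols, arma::fill::zeros);
  arma::mat dX;
  if (need_dx) dX.zeros(Xb.n_rows, Cin);
  for (int i = 0; i < n; ++i) {
    const arma::uword r0 = (arma::uword)i * S, r1 = (arma::uword)(i + 1) * S - 1;
    arma::mat col = im2col_one(Xb.rows(r0, r1), H, W, D, kh, kw, kd);
    arma::mat dYi = dY.rows(r0, r1);
    dW += col.t() * dYi;
    db += arma::sum(dYi, 0).t();
    if (need_dx) {
      arma::mat dcol = dYi * Wmat.t();
      arma::mat dXi(S, Cin, arma::fill::zeros);
      col2im_add(dXi, dcol, H, W, D, kh, kw, kd);
      dX.rows(r0, r1) = dXi;
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Input-side linear map only (used by guided backprop and LRP redistribution).
// [[Rcpp::export(name = ".cxConvInputGrad")]]
arma::mat cx_conv_input_grad(const arma::mat& dY, int n, int H, int W, int D,
                             int kh, int kw, int kd, const arma::mat& Wmat,
                             int cin) {
  const int S = H * W * D;
  arma::mat dX((arma::uword)n * S, cin, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    const arma::uword r0 = (arma::uword)i * S, r1 = (arma::uword)(i + 1) * S - 1;
    arma::mat dcol = dY.rows(r0, r1) * Wmat.t();
    arma::mat dXi(S, cin, arma::fill::zeros);
    col2im_add(dXi, dcol, H, W, D, kh, kw, kd);
    dX.rows(r0, r1) = dXi;
  }
  return dX;
}

// Non-overlapping max pooling (stride = kernel). idx holds 1-based row indices
// into the input batch matrix of the winning position, per output row/channel.
// [[Rcpp::export(name = ".cxMaxPoolFwd")]]
List cx_maxpool_fwd(const arma::mat& Xb, int n, int H, int W, int D,
                    int ph, int pw, int pd) {
  const int S = H * W * D;
  const int C = Xb.n_cols;
  const int H2 = H / ph, W2 = W / pw, D2 = D / pd;
  const int S2 = H2 * W2 * D2;
  arma::mat Y((arma::uword)n * S2, C);
  arma::umat idx((arma::uword)n * S2, C);
  for (int i = 0; i < n; ++i) {
    const arma::uword in0 = (arma::uword)i * S;
    const arma::uword out0 = (arma::uword)i * S2;
    for (int d2 = 0; d2 < D2; ++d2) {
      for (int w2 = 0; w2 < W2; ++w2) {
        for (int h2 = 0; h2 < H2; ++h2) {
          const arma::uword orow = out0 + h2 + H2 * w2 + H2 * W2 * d2;
          for (int c = 0; c < C; ++c) {
            double best = -arma::datum::inf;
            arma::uword bestrow = 0;
            for (int id = 0; id < pd; ++id) {
              for (int iw = 0; iw < pw; ++iw) {
                for (int ih = 0; ih < ph; ++ih) {
                  const int h = h2 * ph + ih, w = w2 * pw + iw, d = d2 * pd + id;
                  const arma::uword r = in0 + h + H * w + H * W * d;
                  const double v = Xb(r, c);
                  if (v > best) { best = v; bestrow = r; }
                }
              }
            }
            Y(orow, c) = best;
            idx(orow, c) = bestrow + 1;
          }
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cxMaxPoolBwd")]]
arma::mat cx_maxpool_bwd(const arma::mat& dY, const arma::umat& idx,
                         int nrow_x) {
  const int C = dY.n_cols;
  arma::mat dX(nrow_x, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (arma::uword r = 0; r < dY.n_rows; ++r)
      dX(idx(r, c) - 1, c) += dY(r, c);
  return dX;
}

// Column-wise affine map: Y[,c] = X[,c] * a[c] + b[c].
// [[Rcpp::export(name = ".cxColAffine")]]
arma::mat cx_col_affine(const arma::mat& X, const arma::vec& a,
                        const arma::vec& b) {
  arma::mat Y(X.n_rows, X.n_cols);
  for (arma::uword c = 0; c < X.n_cols; ++c)
    Y.col(c) = X.col(c) * a(c) + b(c);
  return Y;
}

// Per-column mean and (biased) variance in one pass.
// [[Rcpp::export(name = ".cxColMeanVar")]]
List cx_col_meanvar(const arma::mat& X) {
  arma::rowvec m = arma::mean(X, 0);
  arma::rowvec v = arma::mean(arma::square(X), 0) - arma::square(m);
  return List::create(_["mean"] = m.t(), _["var"] = v.t());
}

// Fused batch-normalization backward pass.
// [[Rcpp::export(name = ".cxBnBwd")]]
List cx_bn_bwd(const arma::mat& G, const arma::mat& xhat,
               const arma::vec& invstd, const arma::vec& gamma,
               bool train) {
  const arma::uword C = G.n_cols;
  arma::vec dgamma(C), dbeta(C);
  arma::mat dX(G.n_rows, C);
  for (arma::uword c = 0; c < C; ++c) {
    const arma::vec g = G.col(c);
    const arma::vec xh = xhat.col(c);
    dgamma(c) = arma::dot(g, xh);
    dbeta(c) = arma::accu(g);
    if (train) {
      const double mg = dbeta(c) / G.n_rows;
      const double mgx = dgamma(c) / G.n_rows;
      dX.col(c) = (g - mg - xh * mgx) * (gamma(c) * invstd(c));
    } else {
      dX.col(c) = g * (gamma(c) * invstd(c));
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

static arma::vec lfilter_zi(const arma::vec& b, const arma::vec& a) {
  const int nn = b.n_elem; // b, a padded to equal length, a(0) == 1
  const int m = nn - 1;
  arma::mat A(m, m, arma::fill::zeros);
  for (int i = 0; i < m; ++i) A(0, i) = -a(i + 1);
  for (int i = 1; i < m; ++i) A(i, i - 1) = 1.0;
  arma::mat I = arma::eye(m, m);
  arma::vec B = b.subvec(1, nn - 1) - a.subvec(1, nn - 1) * b(0);
  return arma::solve(I - A.t(), B);
}

static arma::vec lfilter(const arma::vec& b, const arma::vec& a,
                         const arma::vec& x, const arma::vec& zi) {
  const int nn = b.n_elem;
  arma::vec z = zi;
  arma::vec y(x.n_elem);
  for (arma::uword t = 0; t < x.n_elem; ++t) {
    const double xt = x(t);
    const double yt = b(0) * xt + z(0);
    for (int i = 0; i < nn - 2; ++i)
      z(i) = b(i + 1) * xt + z(i + 1) - a(i + 1) * yt;
    z(nn - 2) = b(nn - 1) * xt - a(nn - 1) * yt;
    y(t) = yt;
  }
  return y;
}

// Zero-phase forward-backward IIR filtering along each column, with odd
// reflective padding and steady-state initial conditions.
// [[Rcpp::export(name = ".cxFiltFilt")]]
arma::mat cx_filtfilt(const arma::mat& X, arma::vec b, arma::vec a) {
  const int nn = std::max(b.n_elem, a.n_elem);
  b.resize(nn); a.resize(nn);
  b /= a(0); a /= a(0);
  const int padlen = 3 * (nn - 1);
  const int T = X.n_rows;
  if (T <= padlen)
    stop("signal too short for filtfilt padding");
  arma::vec zi = lfilter_zi(b, a);
  arma::mat Y(T, X.n_cols);
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    arma::vec x = X.col(c);
    arma::vec ext(T + 2 * padlen);
    for (int i = 0; i < padlen; ++i) ext(i) = 2.0 * x(0) - x(padlen - i);
    ext.subvec(padlen, padlen + T - 1) = x;
    for (int i = 0; i < padlen; ++i)
      ext(padlen + T + i) = 2.0 * x(T - 1) - x(T - 2 - i);
    arma::vec y = lfilter(b, a, ext, zi * ext(0));
    y = arma::reverse(y);
    y = lfilter(b, a, y, zi * y(0));
    y = arma::reverse(y);
    Y.col(c) = y.subvec(padlen, padlen + T - 1);
  }
  return Y;
}
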