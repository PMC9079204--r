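// Numerical kernels for the CNN engine and image geometry.
//
// Tensor layout convention (matches R arrays, column-major):
//   activations  dim = (H, W, C, N)   -> index h + H*(w + W*(c + C*n))
//   conv weights dim = (kh, kw, Ci, Co)
// Convolutions are implemented as im2col + BLAS dgemm; the column buffer is
// reused across samples. All spatial coordinates here are 0-based.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Builds the transposed patch matrix for one sample into a destination
// with arbitrary column stride: column k (= ki + kh*(kj + kw*ci)) of the
// patch matrix starts at dst + k*col_stride and holds P = Ho*Wo entries
// (p = ho + Ho*wo). For stride 1 each column is a set of contiguous
// vertical runs of the source image, so the build is memcpy-bound.
static inline void im2colT_into(const double* x, int H, int W, int Ci,
                                int kh, int kw, int stride,
                                int pad_top, int pad_left,
                                int Ho, int Wo,
                                double* dst, size_t col_stride) {
  for (int ci = 0; ci < Ci; ++ci) {
    const double* xc = x + static_cast<size_t>(H) * W * ci;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* col = dst + col_stride *
          static_cast<size_t>(ki + kh * (kj + kw * ci));
        for (int wo = 0; wo < Wo; ++wo) {
          int c = wo * stride - pad_left + kj;
          double* seg = col + static_cast<size_t>(Ho) * wo;
          if (c < 0 || c >= W) {
            std::fill(seg, seg + Ho, 0.0);
            continue;
          }
          const double* src = xc + static_cast<size_t>(H) * c;
          if (stride == 1) {
            int r0 = -pad_top + ki;              // source row of ho = 0
            int ho_lo = std::max(0, -r0);
            int ho_hi = std::min(Ho, H - r0);    // exclusive
            if (ho_lo > 0) std::fill(seg, seg + std::min(ho_lo, Ho), 0.0);
            if (ho_hi > ho_lo)
              std::copy(src + r0 + ho_lo, src + r0 + ho_hi, seg + ho_lo);
            if (ho_hi < Ho) std::fill(seg + std::max(ho_hi, 0), seg + Ho, 0.0);
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              int r = ho * stride - pad_top + ki;
              seg[ho] = (r >= 0 && r < H) ? src[r] : 0.0;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cg_conv_fwd(NumericVector x, IntegerVector xdim,
                          NumericVector w, IntegerVector wdim,
                          NumericVector b, int stride,
                          int pad_top, int pad_left, int Ho, int Wo) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Co = wdim[3];
  const int K = kh * kw * Ci, P = Ho * Wo;
  NumericVector y(static_cast<R_xlen_t>(P) * Co * N);
  arma::mat Wm(w.begin(), K, Co, false, true);
  arma::mat colT(P, K);
  arma::rowvec bv(b.begin(), Co);
  for (int n = 0; n < N; ++n) {
    im2colT_into(x.begin() + static_cast<R_xlen_t>(n) * H * W * Ci,
                 H, W, Ci, kh, kw, stride, pad_top, pad_left, Ho, Wo,
                 colT.memptr(), P);
    arma::mat Ym(y.begin() + static_cast<R_xlen_t>(n) * P * Co, P, Co, false, true);
    Ym = colT * Wm;
    Ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cg_conv_bwd(NumericVector x, IntegerVector xdim,
                 NumericVector w, IntegerVector wdim,
                 NumericVector dy, int stride,
                 int pad_top, int pad_left, int Ho, int Wo) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Co = wdim[3];
  const int K = kh * kw * Ci, P = Ho * Wo;
  NumericVector dx(x.size());
  NumericVector dw(w.size());
  NumericVector db(Co);
  arma::mat Wm(w.begin(), K, Co, false, true);
  arma::mat dWm(dw.begin(), K, Co, false, true);
  arma::vec dbv(db.begin(), Co, false, true);
  arma::mat colT(P, K), dcolT(P, K);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + static_cast<R_xlen_t>(n) * H * W * Ci;
    double* dxs = dx.begin() + static_cast<R_xlen_t>(n) * H * W * Ci;
    arma::mat dYm(const_cast<double*>(dy.begin()) +
                    static_cast<R_xlen_t>(n) * P * Co, P, Co, false, true);
    im2colT_into(xs, H, W, Ci, kh, kw, stride, pad_top, pad_left, Ho, Wo,
                 colT.memptr(), P);
    dWm += colT.t() * dYm;
    dbv += arma::sum(dYm, 0).t();
    dcolT = dYm * Wm.t();   // P x K
    // col2im scatter-add, contiguous vertical runs for stride 1
    for (int ci = 0; ci < Ci; ++ci) {
      double* dxc = dxs + static_cast<size_t>(H) * W * ci;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const double* srcall = dcolT.colptr(ki + kh * (kj + kw * ci));
          for (int wo = 0; wo < Wo; ++wo) {
            int c = wo * stride - pad_left + kj;
            if (c < 0 || c >= W) continue;
            const double* seg = srcall + static_cast<size_t>(Ho) * wo;
            double* dst = dxc + static_cast<size_t>(H) * c;
            if (stride == 1) {
              int r0 = -pad_top + ki;
              int ho_lo = std::max(0, -r0);
              int ho_hi = std::min(Ho, H - r0);
              for (int ho = ho_lo; ho < ho_hi; ++ho) dst[r0 + ho] += seg[ho];
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                int r = ho * stride - pad_top + ki;
                if (r >= 0 && r < H) dst[r] += seg[ho];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cg_dwconv_fwd(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            NumericVector b, int stride,
                            int pad_top, int pad_left, int Ho, int Wo) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1];
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + static_cast<R_xlen_t>(H) * W * (c + C * n);
      const double* wc = w.begin() + static_cast<R_xlen_t>(kh) * kw * c;
      double* ys = y.begin() + static_cast<R_xlen_t>(Ho) * Wo * (c + C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = b[c];
          for (int kj = 0; kj < kw; ++kj) {
            int cc = wo * stride - pad_left + kj;
            if (cc < 0 || cc >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int rr = ho * stride - pad_top + ki;
              if (rr < 0 || rr >= H) continue;
              acc += xs[rr + H * cc] * wc[ki + kh * kj];
            }
          }
          ys[ho + Ho * wo] = acc;
        }
    }
  return y;
}

// [[Rcpp::export]]
List cg_dwconv_bwd(NumericVector x, IntegerVector xdim,
                   NumericVector w, IntegerVector wdim,
                   NumericVector dy, int stride,
                   int pad_top, int pad_left, int Ho, int Wo) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1];
  NumericVector dx(x.size()), dw(w.size()), db(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + static_cast<R_xlen_t>(H) * W * (c + C * n);
      double* dxs = dx.begin() + static_cast<R_xlen_t>(H) * W * (c + C * n);
      const double* wc = w.begin() + static_cast<R_xlen_t>(kh) * kw * c;
      double* dwc = dw.begin() + static_cast<R_xlen_t>(kh) * kw * c;
      const double* dys = dy.begin() + static_cast<R_xlen_t>(Ho) * Wo * (c + C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = dys[ho + Ho * wo];
          db[c] += g;
          for (int kj = 0; kj < kw; ++kj) {
            int cc = wo * stride - pad_left + kj;
            if (cc < 0 || cc >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int rr = ho * stride - pad_top + ki;
              if (rr < 0 || rr >= H) continue;
              dwc[ki + kh * kj] += xs[rr + H * cc] * g;
              dxs[rr + H * cc] += wc[ki + kh * kj] * g;
            }
          }
        }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// mode: 0 = average (divides by k*k; zero padding contributes zeros),
//       1 = max over in-bounds positions.
// [[Rcpp::export]]
NumericVector cg_pool_fwd(NumericVector x, IntegerVector xdim,
                          int k, int stride, int pad_top, int pad_left,
                          int Ho, int Wo, int mode) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + static_cast<R_xlen_t>(H) * W * (c + C * n);
      double* ys = y.begin() + static_cast<R_xlen_t>(Ho) * Wo * (c + C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = (mode == 0) ? 0.0 : R_NegInf;
          bool any = false;
          for (int kj = 0; kj < k; ++kj) {
            int cc = wo * stride - pad_left + kj;
            if (cc < 0 || cc >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int rr = ho * stride - pad_top + ki;
              if (rr < 0 || rr >= H) continue;
              double v = xs[rr + H * cc];
              any = true;
              if (mode == 0) acc += v; else if (v > acc) acc = v;
            }
          }
          if (mode == 0) acc /= (double)(k * k);
          ys[ho + Ho * wo] = any ? acc : 0.0;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cg_pool_bwd(NumericVector x, IntegerVector xdim,
                          NumericVector dy, int k, int stride,
                          int pad_top, int pad_left, int Ho, int Wo, int mode) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector dx(x.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + static_cast<R_xlen_t>(H) * W * (c + C * n);
      double* dxs = dx.begin() + static_cast<R_xlen_t>(H) * W * (c + C * n);
      const double* dys = dy.begin() + static_cast<R_xlen_t>(Ho) * Wo * (c + C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = dys[ho + Ho * wo];
          if (g == 0.0) continue;
          if (mode == 0) {
            double share = g / (double)(k * k);
            for (int kj = 0; kj < k; ++kj) {
              int cc = wo * stride - pad_left + kj;
              if (cc < 0 || cc >= W) continue;
              for (int ki = 0; ki < k; ++ki) {
                int rr = ho * stride - pad_top + ki;
                if (rr < 0 || rr >= H) continue;
                dxs[rr + H * cc] += share;
              }
            }
          } else {
            int br = -1, bc = -1; double best = R_NegInf;
            for (int kj = 0; kj < k; ++kj) {
              int cc = wo * stride - pad_left + kj;
              if (cc < 0 || cc >= W) continue;
              for (int ki = 0; ki < k; ++ki) {
                int rr = ho * stride - pad_top + ki;
                if (rr < 0 || rr >= H) continue;
                double v = xs[rr + H * cc];
                if (v > best) { best = v; br = rr; bc = cc; }
              }
            }
            if (br >= 0) dxs[br + H * bc] += g;
          }
        }
    }
  return dx;
}

static inline double bilinear_at(const NumericMatrix& img, double r, double c) {
  const int H = img.nrow(), W = img.ncol();
  if (r <= -1.0 || c <= -1.0 || r >= (double)H || c >= (double)W) return 0.0;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double fr = r - r0, fc = c - c0;
  double v00 = (r0 >= 0 && r0 < H && c0 >= 0 && c0 < W) ? img(r0, c0) : 0.0;
  double v01 = (r0 >= 0 && r0 < H && c0 + 1 >= 0 && c0 + 1 < W) ? img(r0, c0 + 1) : 0.0;
  double v10 = (r0 + 1 >= 0 && r0 + 1 < H && c0 >= 0 && c0 < W) ? img(r0 + 1, c0) : 0.0;
  double v11 = (r0 + 1 >= 0 && r0 + 1 < H && c0 + 1 >= 0 && c0 + 1 < W) ? img(r0 + 1, c0 + 1) : 0.0;
  return v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
         v10 * fr * (1 - fc) + v11 * fr * fc;
}

// Inverse-mapping affine warp: for each output pixel (r, c) (0-based) the
// source location is (m[0]*r + m[1]*c + m[2], m[3]*r + m[4]*c + m[5]);
// bilinear interpolation, zero fill outside the source frame.
// [[Rcpp::export]]
NumericMatrix cg_warp_affine(NumericMatrix img, NumericVector m) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double sr = m[0] * r + m[1] * c + m[2];
      double sc = m[3] * r + m[4] * c + m[5];
      out(r, c) = bilinear_at(img, sr, sc);
    }
  return out;
}

// Bilinear resize with half-pixel center alignment (align_corners = false).
// [[Rcpp::export]]
NumericMatrix cg_resize_bilinear(NumericMatrix img, int h2, int w2) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(h2, w2);
  const double sr = (double)H / h2, sc = (double)W / w2;
  for (int c = 0; c < w2; ++c)
    for (int r = 0; r < h2; ++r) {
      double y = (r + 0.5) * sr - 0.5;
      double x = (c + 0.5) * sc - 0.5;
      if (y < 0) y = 0; if (y > H - 1) y = H - 1;
      if (x < 0) x = 0; if (x > W - 1) x = W - 1;
      out(r, c) = bilinear_at(img, y, x);
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cg_relu(NumericVector x) {
  NumericVector y(x.size());
  const double* xs = x.begin(); double* ys = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) ys[i] = xs[i] > 0 ? xs[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// dout * (out > 0), the ReLU gradient mask applied without intermediates.
// [[Rcpp::export]]
NumericVector cg_relu_bwd(NumericVector dout, NumericVector out) {
  NumericVector g(dout.size());
  const double* d = dout.begin(); const double* o = out.begin();
  double* gs = g.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i) gs[i] = o[i] > 0 ? d[i] : 0.0;
  g.attr("dim") = dout.attr("dim");
  return g;
}
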