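// Low-level numerical kernels for the autograd engine.
//
// Tensor layout: R numeric arrays with dim (H, W, C, N), column-major, so the
// linear index of (h, w, c, n) is h + H*(w + W*(c + C*n)).  Convolution
// weights have dim (kh, kw, Cin, Cout).  All convolutions use zero padding.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// im2col: columns indexed by output pixel (ho, wo, n); rows by (i, j, c)
// with i fastest — matching the column-major flattening of the weight array.
static arma::mat im2col(const double* x, int H, int W, int C, int N,
                        int kh, int kw, int stride, int pad,
                        int Ho, int Wo) {
  const int K = kh * kw * C;
  const long M = (long)Ho * Wo * N;
  arma::mat cols(K, M, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const long m = ho + (long)Ho * (wo + (long)Wo * n);
        double* col = cols.colptr(m);
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double* xc = x + (long)H * W * (c + (long)C * n);
          for (int j = 0; j < kw; ++j) {
            const int wi = w0 + j;
            for (int i = 0; i < kh; ++i) {
              const int hi = h0 + i;
              double v = 0.0;
              if (hi >= 0 && hi < H && wi >= 0 && wi < W)
                v = xc[hi + (long)H * wi];
              col[i + kh * (j + kw * c)] = v;
            }
          }
        }
      }
    }
  }
  return cols;
}

// col2im: scatter-add adjoint of im2col.
static void col2im(const arma::mat& cols, double* x, int H, int W, int C, int N,
                   int kh, int kw, int stride, int pad, int Ho, int Wo) {
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const long m = ho + (long)Ho * (wo + (long)Wo * n);
        const double* col = cols.colptr(m);
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          double* xc = x + (long)H * W * (c + (long)C * n);
          for (int j = 0; j < kw; ++j) {
            const int wi = w0 + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = h0 + i;
              if (hi < 0 || hi >= H) continue;
              xc[hi + (long)H * wi] += col[i + kh * (j + kw * c)];
            }
          }
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w,
                           int stride, int pad) {
  IntegerVector dx = dims4(x), dw = dims4(w);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Ci = dw[2], Co = dw[3];
  if (Ci != C) stop("channel mismatch in conv");
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv output would be empty");
  arma::mat cols = im2col(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Ci, Co, false, true);
  arma::mat Y = Wm.t() * cols; // (Co, M)
  NumericVector out((long)Ho * Wo * Co * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  double* o = out.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const long m = ho + (long)Ho * (wo + (long)Wo * n);
        for (int co = 0; co < Co; ++co)
          o[ho + (long)Ho * (wo + (long)Wo * (co + (long)Co * n))] = Y(co, m);
      }
  return out;
}

// Gradient w.r.t. conv input; also the forward pass of a transposed conv
// (then x plays the role of dy and H,W are the *output* spatial dims).
// [[Rcpp::export]]
NumericVector cpp_conv_bwd_data(NumericVector dy, NumericVector w,
                                int stride, int pad, int H, int W) {
  IntegerVector dd = dims4(dy), dw = dims4(w);
  const int Ho = dd[0], Wo = dd[1], Co = dd[2], N = dd[3];
  const int kh = dw[0], kw = dw[1], Ci = dw[2], Cw = dw[3];
  if (Cw != Co) stop("channel mismatch in conv_bwd_data");
  arma::mat dYm(Co, (long)Ho * Wo * N, arma::fill::zeros);
  {
    const double* d = dy.begin();
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Co; ++co)
        for (int wo = 0; wo < Wo; ++wo)
          for (int ho = 0; ho < Ho; ++ho)
            dYm(co, ho + (long)Ho * (wo + (long)Wo * n)) =
              d[ho + (long)Ho * (wo + (long)Wo * (co + (long)Co * n))];
  }
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Ci, Co, false, true);
  arma::mat dcols = Wm * dYm; // (K, M)
  NumericVector out((long)H * W * Ci * N);
  out.attr("dim") = IntegerVector::create(H, W, Ci, N);
  std::fill(out.begin(), out.end(), 0.0);
  col2im(dcols, out.begin(), H, W, Ci, N, kh, kw, stride, pad, Ho, Wo);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv_bwd_weight(NumericVector x, NumericVector dy,
                                  int stride, int pad, int kh, int kw) {
  IntegerVector dx = dims4(x), dd = dims4(dy);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = dd[0], Wo = dd[1], Co = dd[2];
  arma::mat cols = im2col(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  arma::mat dYm(Co, (long)Ho * Wo * N);
  {
    const double* d = dy.begin();
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Co; ++co)
        for (int wo = 0; wo < Wo; ++wo)
          for (int ho = 0; ho < Ho; ++ho)
            dYm(co, ho + (long)Ho * (wo + (long)Wo * n)) =
              d[ho + (long)Ho * (wo + (long)Wo * (co + (long)Co * n))];
  }
  arma::mat dW = cols * dYm.t(); // (K, Co)
  NumericVector out((long)kh * kw * C * Co);
  out.attr("dim") = IntegerVector::create(kh, kw, C, Co);
  std::copy(dW.begin(), dW.end(), out.begin());
  return out;
}

// Bilinear resize, align_corners = false (half-pixel centers), edge clamp.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int oh, int ow) {
  IntegerVector dx = dims4(x);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  NumericVector out((long)oh * ow * C * N);
  out.attr("dim") = IntegerVector::create(oh, ow, C, N);
  const double sh = (double)H / oh, sw = (double)W / ow;
  const double* xp = x.begin();
  double* o = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (long)H * W * (c + (long)C * n);
      double* oc = o + (long)oh * ow * (c + (long)C * n);
      for (int wo = 0; wo < ow; ++wo) {
        double xs = (wo + 0.5) * sw - 0.5;
        if (xs < 0) xs = 0; if (xs > W - 1) xs = W - 1;
        const int x0 = (int)xs, x1 = std::min(x0 + 1, W - 1);
        const double fx = xs - x0;
        for (int ho = 0; ho < oh; ++ho) {
          double ys = (ho + 0.5) * sh - 0.5;
          if (ys < 0) ys = 0; if (ys > H - 1) ys = H - 1;
          const int y0 = (int)ys, y1 = std::min(y0 + 1, H - 1);
          const double fy = ys - y0;
          oc[ho + (long)oh * wo] =
            (1 - fy) * ((1 - fx) * xc[y0 + (long)H * x0] + fx * xc[y0 + (long)H * x1]) +
            fy * ((1 - fx) * xc[y1 + (long)H * x0] + fx * xc[y1 + (long)H * x1]);
        }
      }
    }
  return out;
}

// Adjoint of cpp_resize_bilinear: scatter dy back to an (h, w) grid.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector dy, int h, int w) {
  IntegerVector dd = dims4(dy);
  const int Ho = dd[0], Wo = dd[1], C = dd[2], N = dd[3];
  NumericVector out((long)h * w * C * N);
  out.attr("dim") = IntegerVector::create(h, w, C, N);
  std::fill(out.begin(), out.end(), 0.0);
  const double sh = (double)h / Ho, sw = (double)w / Wo;
  const double* d = dy.begin();
  double* o = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* oc = o + (long)h * w * (c + (long)C * n);
      const double* dc = d + (long)Ho * Wo * (c + (long)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        double xs = (wo + 0.5) * sw - 0.5;
        if (xs < 0) xs = 0; if (xs > w - 1) xs = w - 1;
        const int x0 = (int)xs, x1 = std::min(x0 + 1, w - 1);
        const double fx = xs - x0;
        for (int ho = 0; ho < Ho; ++ho) {
          double ys = (ho + 0.5) * sh - 0.5;
          if (ys < 0) ys = 0; if (ys > h - 1) ys = h - 1;
          const int y0 = (int)ys, y1 = std::min(y0 + 1, h - 1);
          const double fy = ys - y0;
          const double g = dc[ho + (long)Ho * wo];
          oc[y0 + (long)h * x0] += (1 - fy) * (1 - fx) * g;
          oc[y0 + (long)h * x1] += (1 - fy) * fx * g;
          oc[y1 + (long)h * x0] += fy * (1 - fx) * g;
          oc[y1 + (long)h * x1] += fy * fx * g;
        }
      }
    }
  return out;
}

// Horizontal STN warp: out(h, w) = img(h, w + sign * d(h, w)) with bilinear
// interpolation in x and edge clamping.  disp has dim (H, W, 1, N).
// [[Rcpp::export]]
NumericVector cpp_warp_h_fwd(NumericVector img, NumericVector disp, double sign) {
  IntegerVector di = dims4(img), dd = dims4(disp);
  const int H = di[0], W = di[1], C = di[2], N = di[3];
  if (dd[0] != H || dd[1] != W || dd[2] != 1 || dd[3] != N)
    stop("disparity must have dim (H, W, 1, N) matching the image");
  NumericVector out((long)H * W * C * N);
  out.attr("dim") = di;
  const double* ip = img.begin();
  const double* dp = disp.begin();
  double* o = out.begin();
  for (int n = 0; n < N; ++n) {
    const double* dn = dp + (long)H * W * n;
    for (int c = 0; c < C; ++c) {
      const double* ic = ip + (long)H * W * (c + (long)C * n);
      double* oc = o + (long)H * W * (c + (long)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double xs = w + sign * dn[h + (long)H * w];
          if (xs < 0) xs = 0; if (xs > W - 1) xs = W - 1;
          const int x0 = (int)xs, x1 = std::min(x0 + 1, W - 1);
          const double fx = xs - x0;
          oc[h + (long)H * w] =
            (1 - fx) * ic[h + (long)H * x0] + fx * ic[h + (long)H * x1];
        }
    }
  }
  return out;
}

// Backward of the horizontal warp w.r.t. both the source image and the
// disparity.  d out / d xs = img(x1) - img(x0); zero where clamped flat.
// [[Rcpp::export]]
List cpp_warp_h_bwd(NumericVector img, NumericVector disp, double sign,
                    NumericVector dy) {
  IntegerVector di = dims4(img);
  const int H = di[0], W = di[1], C = di[2], N = di[3];
  NumericVector dimg((long)H * W * C * N), ddisp((long)H * W * N);
  dimg.attr("dim") = di;
  ddisp.attr("dim") = IntegerVector::create(H, W, 1, N);
  std::fill(dimg.begin(), dimg.end(), 0.0);
  std::fill(ddisp.begin(), ddisp.end(), 0.0);
  const double* ip = img.begin();
  const double* dp = disp.begin();
  const double* g = dy.begin();
  for (int n = 0; n < N; ++n) {
    const double* dn = dp + (long)H * W * n;
    double* ddn = ddisp.begin() + (long)H * W * n;
    for (int c = 0; c < C; ++c) {
      const double* ic = ip + (long)H * W * (c + (long)C * n);
      double* dic = dimg.begin() + (long)H * W * (c + (long)C * n);
      const double* gc = g + (long)H * W * (c + (long)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double raw = w + sign * dn[h + (long)H * w];
          double xs = raw;
          bool clamped = false;
          if (xs < 0) { xs = 0; clamped = true; }
          if (xs > W - 1) { xs = W - 1; clamped = true; }
          const int x0 = (int)xs, x1 = std::min(x0 + 1, W - 1);
          const double fx = xs - x0;
          const double gg = gc[h + (long)H * w];
          dic[h + (long)H * x0] += (1 - fx) * gg;
          dic[h + (long)H * x1] += fx * gg;
          if (!clamped)
            ddn[h + (long)H * w] +=
              gg * sign * (ic[h + (long)H * x1] - ic[h + (long)H * x0]);
        }
    }
  }
  return List::create(_["dimg"] = dimg, _["ddisp"] = ddisp);
}

// Normalized k x k box filter with zero padding and per-pixel valid-count
// normalization.  adjoint = true computes the exact transpose (divide each
// pixel's gradient by its count before the summation).
// [[Rcpp::export]]
NumericVector cpp_boxblur(NumericVector x, int k, bool adjoint) {
  IntegerVector dx = dims4(x);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int r = k / 2;
  NumericVector out((long)H * W * C * N);
  out.attr("dim") = dx;
  std::fill(out.begin(), out.end(), 0.0);
  // precompute per-pixel neighbour counts
  std::vector<double> cnt((long)H * W);
  for (int w = 0; w < W; ++w) {
    const int wl = std::max(0, w - r), wr = std::min(W - 1, w + r);
    for (int h = 0; h < H; ++h) {
      const int ht = std::max(0, h - r), hb = std::min(H - 1, h + r);
      cnt[h + (long)H * w] = (double)(wr - wl + 1) * (hb - ht + 1);
    }
  }
  const double* xp = x.begin();
  double* o = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (long)H * W * (c + (long)C * n);
      double* oc = o + (long)H * W * (c + (long)C * n);
      for (int w = 0; w < W; ++w) {
        const int wl = std::max(0, w - r), wr = std::min(W - 1, w + r);
        for (int h = 0; h < H; ++h) {
          const int ht = std::max(0, h - r), hb = std::min(H - 1, h + r);
          double s = 0.0;
          if (!adjoint) {
            for (int ww = wl; ww <= wr; ++ww)
              for (int hh = ht; hh <= hb; ++hh)
                s += xc[hh + (long)H * ww];
            oc[h + (long)H * w] = s / cnt[h + (long)H * w];
          } else {
            for (int ww = wl; ww <= wr; ++ww)
              for (int hh = ht; hh <= hb; ++hh)
                s += xc[hh + (long)H * ww] / cnt[hh + (long)H * ww];
            oc[h + (long)H * w] = s;
          }
        }
      }
    }
  return out;
}
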