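// Numeric kernels: 2-D convolution (im2col + GEMM), pooling, resampling,
// separable smoothing, and connected-component labelling.  Feature maps are
// dense arrays in R's column-major layout with dim (H, W, C, N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline NumericVector make4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline arma::cube cube_view(const NumericVector& x, int H, int W, int C,
                                   int n) {
  // no-copy view of sample n of an (H, W, C, N) array
  return arma::cube(const_cast<double*>(x.begin()) + (size_t)n * H * W * C, H,
                    W, C, false, true);
}

// col is laid out (H*W) x (kh*kw*C): each kernel tap is one contiguous
// column, so both the gather here and the GEMMs read/write sequentially.
static void im2col(const arma::cube& xs, int kh, int kw, int dil,
                   arma::mat& col) {
  const int H = xs.n_rows, W = xs.n_cols, C = xs.n_slices;
  const int ch = dil * (kh - 1) / 2, cw = dil * (kw - 1) / 2;
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < kw; ++b)
      for (int a = 0; a < kh; ++a) {
        const int r = a + kh * (b + kw * c);
        const int di = dil * a - ch, dj = dil * b - cw;
        double* dst = col.colptr(r);
        for (int j = 0; j < W; ++j, dst += H) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = xs.slice_colptr(c, sj) + di;
          const int lo = std::max(0, -di), hi = std::min(H, H - di);
          if (lo > 0) std::fill(dst, dst + lo, 0.0);
          if (hi < H) std::fill(dst + hi, dst + H, 0.0);
          std::copy(src + lo, src + hi, dst + lo);
        }
      }
}

static void col2im_add(const arma::mat& col, int kh, int kw, int dil,
                       arma::cube& xs) {
  const int H = xs.n_rows, W = xs.n_cols, C = xs.n_slices;
  const int ch = dil * (kh - 1) / 2, cw = dil * (kw - 1) / 2;
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < kw; ++b)
      for (int a = 0; a < kh; ++a) {
        const int r = a + kh * (b + kw * c);
        const int di = dil * a - ch, dj = dil * b - cw;
        const double* src = col.colptr(r);
        for (int j = 0; j < W; ++j, src += H) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          double* dst = xs.slice_colptr(c, sj) + di;
          const int lo = std::max(0, -di), hi = std::min(H, H - di);
          for (int i = lo; i < hi; ++i) dst[i] += src[i];
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector bias, int dil) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("conv2d: channel mismatch (%d vs %d)", Cin, C);
  const int K = kh * kw * Cin;
  arma::mat wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::colvec bv(const_cast<double*>(bias.begin()), Cout, false, true);

  NumericVector y = make4(H, W, Cout, N);
  arma::mat col((size_t)H * W, K);
  for (int n = 0; n < N; ++n) {
    arma::cube xs = cube_view(x, H, W, C, n);
    im2col(xs, kh, kw, dil, col);
    arma::mat ym(y.begin() + (size_t)n * H * W * Cout, (size_t)H * W, Cout,
                 false, true);
    ym = col * wmat;
    ym.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int dil) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cin = dw[2], Cout = dw[3];
  const int K = kh * kw * Cin;
  arma::mat wmat(const_cast<double*>(w.begin()), K, Cout, false, true);

  NumericVector gx = make4(H, W, C, N);
  NumericVector gw = make4(kh, kw, Cin, Cout);
  NumericVector gb(Cout);
  arma::mat gwm(gw.begin(), K, Cout, false, true);
  arma::colvec gbv(gb.begin(), Cout, false, true);
  arma::mat col((size_t)H * W, K);
  for (int n = 0; n < N; ++n) {
    arma::cube xs = cube_view(x, H, W, C, n);
    im2col(xs, kh, kw, dil, col);
    arma::mat gym(const_cast<double*>(gy.begin()) + (size_t)n * H * W * Cout,
                  (size_t)H * W, Cout, false, true);
    gwm += col.t() * gym;
    gbv += arma::sum(gym, 0).t();
    arma::mat gcol = gym * wmat.t();  // (H*W) x K
    arma::cube gxs(gx.begin() + (size_t)n * H * W * C, H, W, C, false, true);
    col2im_add(gcol, kh, kw, dil, gxs);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_avgpool(NumericVector x, int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / k, Wo = W / k;
  NumericVector y = make4(Ho, Wo, C, N);
  const double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = x.begin() + ((size_t)n * C + c) * H * W;
      double* dst = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double s = 0;
          for (int b = 0; b < k; ++b)
            for (int a = 0; a < k; ++a)
              s += src[(size_t)(j * k + b) * H + i * k + a];
          dst[(size_t)j * Ho + i] = s * inv;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector gy, int k) {
  IntegerVector d = gy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const int H = Ho * k, W = Wo * k;
  NumericVector gx = make4(H, W, C, N);
  const double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = gy.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* dst = gx.begin() + ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const double g = src[(size_t)j * Ho + i] * inv;
          for (int b = 0; b < k; ++b)
            for (int a = 0; a < k; ++a)
              dst[(size_t)(j * k + b) * H + i * k + a] = g;
        }
    }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nn(NumericVector x, int f) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H * f, Wo = W * f;
  NumericVector y = make4(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = x.begin() + ((size_t)n * C + c) * H * W;
      double* dst = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          dst[(size_t)j * Ho + i] = src[(size_t)(j / f) * H + i / f];
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nn_bwd(NumericVector gy, int f) {
  IntegerVector d = gy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const int H = Ho / f, W = Wo / f;
  NumericVector gx = make4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = gy.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* dst = gx.begin() + ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          dst[(size_t)(j / f) * H + i / f] += src[(size_t)j * Ho + i];
    }
  return gx;
}

// Separable correlation with an odd symmetric kernel, replicate padding.
// [[Rcpp::export]]
NumericMatrix cpp_sep_filter(NumericMatrix x, NumericVector kern) {
  const int H = x.nrow(), W = x.ncol(), K = kern.size(), r = (K - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int a = -r; a <= r; ++a) {
        int ii = std::min(std::max(i + a, 0), H - 1);
        s += kern[a + r] * x(ii, j);
      }
      tmp(i, j) = s;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int a = -r; a <= r; ++a) {
        int jj = std::min(std::max(j + a, 0), W - 1);
        s += kern[a + r] * tmp(i, jj);
      }
      out(i, j) = s;
    }
  return out;
}

// 8-connected components of (mask == value); returns integer labels, 0 = off.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int value) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j0 = 0; j0 < W; ++j0)
    for (int i0 = 0; i0 < H; ++i0) {
      if (mask(i0, j0) != value || lab(i0, j0) != 0) continue;
      ++next;
      stack.push_back(j0 * H + i0);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int i = p % H, j = p / H;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) == value && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(jj * H + ii);
            }
          }
      }
    }
  return lab;
}

// ---- batch-norm / SiLU kernels (single pass over (H,W,C,N) arrays) --------

// [[Rcpp::export]]
List cpp_channel_stats(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const size_t HW = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector mu(C), m2(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)n * C + c) * HW;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < HW; ++i) {
        s += p[i];
        s2 += p[i] * p[i];
      }
      mu[c] += s;
      m2[c] += s2;
    }
  const double inv = 1.0 / ((double)HW * N);
  for (int c = 0; c < C; ++c) {
    mu[c] *= inv;
    m2[c] *= inv;
  }
  return List::create(_["mean"] = mu, _["meansq"] = m2);
}

// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector mu, NumericVector istd,
                NumericVector gamma, NumericVector beta) {
  IntegerVector d = x.attr("dim");
  const size_t HW = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector xhat = make4(d[0], d[1], C, N), y = make4(d[0], d[1], C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double m = mu[c], is = istd[c], g = gamma[c], b = beta[c];
      const double* p = x.begin() + ((size_t)n * C + c) * HW;
      double* ph = xhat.begin() + ((size_t)n * C + c) * HW;
      double* py = y.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        const double h = (p[i] - m) * is;
        ph[i] = h;
        py[i] = g * h + b;
      }
    }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector gy, NumericVector xhat, NumericVector gamma,
                NumericVector istd, bool training) {
  IntegerVector d = gy.attr("dim");
  const size_t HW = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector gx = make4(d[0], d[1], C, N);
  NumericVector ggamma(C), gbeta(C), m1(C), m2(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* pg = gy.begin() + ((size_t)n * C + c) * HW;
      const double* ph = xhat.begin() + ((size_t)n * C + c) * HW;
      double s1 = 0, s2 = 0;
      for (size_t i = 0; i < HW; ++i) {
        s1 += pg[i];
        s2 += pg[i] * ph[i];
      }
      gbeta[c] += s1;
      ggamma[c] += s2;
    }
  const double inv = 1.0 / ((double)HW * N);
  for (int c = 0; c < C; ++c) {
    m1[c] = training ? gbeta[c] * inv : 0.0;
    m2[c] = training ? ggamma[c] * inv : 0.0;
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double a = gamma[c] * istd[c], mm1 = m1[c], mm2 = m2[c];
      const double* pg = gy.begin() + ((size_t)n * C + c) * HW;
      const double* ph = xhat.begin() + ((size_t)n * C + c) * HW;
      double* px = gx.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i)
        px[i] = a * (pg[i] - mm1 - ph[i] * mm2);
    }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
List cpp_silu_fwd(NumericVector x) {
  NumericVector y(x.size()), s(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double sv = 1.0 / (1.0 + std::exp(-x[i]));
    s[i] = sv;
    y[i] = x[i] * sv;
  }
  return List::create(_["y"] = y, _["s"] = s);
}

// [[Rcpp::export]]
NumericVector cpp_silu_bwd(NumericVector gy, NumericVector s,
                           NumericVector x) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    gx[i] = gy[i] * (s[i] * (1.0 + x[i] * (1.0 - s[i])));
  return gx;
}
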