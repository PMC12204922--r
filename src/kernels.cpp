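// Numerical kernels for the convolutional network: conv2d (im2col + GEMM),
// max pooling, bilinear upsampling and batch normalization, each with an
// explicit backward pass.  Tensor layout everywhere is an R array with
// dim = c(H, W, C, N), column-major (H fastest).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// im2col, pixel-major: colsT(p, r) with p = h + H*w and
// r = ki + KH*kj + KH*KW*cin, stride 1, symmetric zero padding (KH-1)/2.
static void im2colT(const double* x, int n, int H, int W, int C,
                    int KH, int KW, arma::mat& colsT) {
  const int padh = (KH - 1) / 2, padw = (KW - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * (c + C * n);
    for (int kj = 0; kj < KW; ++kj) {
      for (int ki = 0; ki < KH; ++ki) {
        const int r = ki + KH * kj + KH * KW * c;
        double* dst = colsT.colptr(r);
        for (int w = 0; w < W; ++w) {
          const int sw = w + kj - padw;
          double* d = dst + (size_t)H * w;
          if (sw < 0 || sw >= W) {
            for (int h = 0; h < H; ++h) d[h] = 0.0;
          } else {
            const double* s = xc + (size_t)H * sw;
            for (int h = 0; h < H; ++h) {
              const int sh = h + ki - padh;
              d[h] = (sh < 0 || sh >= H) ? 0.0 : s[sh];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  const int HW = H * W, R = KH * KW * Cin;
  NumericVector y((size_t)HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), R, Cout, false, true);
  arma::mat colsT(HW, R);
  for (int n = 0; n < N; ++n) {
    im2colT(x.begin(), n, H, W, C, KH, KW, colsT);
    arma::mat out = colsT * Wm;                  // HW x Cout
    for (int co = 0; co < Cout; ++co) {
      double* dst = y.begin() + (size_t)HW * (co + Cout * n);
      const double* src = out.colptr(co);
      const double bias = b[co];
      for (int p = 0; p < HW; ++p) dst[p] = src[p] + bias;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  const int HW = H * W, R = KH * KW * Cin;
  const int padh = (KH - 1) / 2, padw = (KW - 1) / 2;
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), R, Cout, false, true);
  arma::mat dWm(dw.begin(), R, Cout, false, true);
  arma::mat colsT(HW, R);
  for (int n = 0; n < N; ++n) {
    arma::mat Dy(HW, Cout);
    for (int co = 0; co < Cout; ++co) {
      const double* src = dy.begin() + (size_t)HW * (co + Cout * n);
      double s = 0.0;
      for (int p = 0; p < HW; ++p) { Dy(p, co) = src[p]; s += src[p]; }
      db[co] += s;
    }
    im2colT(x.begin(), n, H, W, C, KH, KW, colsT);
    dWm += colsT.t() * Dy;
    arma::mat dCt = Dy * Wm.t();                 // HW x R
    // scatter-add back to dx, pixel-contiguous in both source and target
    for (int c = 0; c < C; ++c) {
      double* dxc = dx.begin() + (size_t)H * W * (c + C * n);
      for (int kj = 0; kj < KW; ++kj)
        for (int ki = 0; ki < KH; ++ki) {
          const int r = ki + KH * kj + KH * KW * c;
          const double* g = dCt.colptr(r);
          for (int w2 = 0; w2 < W; ++w2) {
            const int sw = w2 + kj - padw;
            if (sw < 0 || sw >= W) continue;
            double* d = dxc + (size_t)H * sw;
            const double* gp = g + (size_t)H * w2;
            const int h0 = std::max(0, padh - ki);
            const int h1 = std::min(H, H + padh - ki);
            for (int h = h0; h < h1; ++h) d[h + ki - padh] += gp[h];
          }
        }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / k, Wo = W / k;
  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(y.size());
  int p = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++p) {
          double best = -1e300; int bi = -1;
          for (int dj = 0; dj < k; ++dj)
            for (int di = 0; di < k; ++di) {
              const int ii = idx4(h * k + di, w * k + dj, c, n, H, W, C);
              if (x[ii] > best) { best = x[ii]; bi = ii; }
            }
          // y is in (h fastest) order only within its own layout; compute index
          y[idx4(h, w, c, n, Ho, Wo, C)] = best;
          arg[idx4(h, w, c, n, Ho, Wo, C)] = bi;
        }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(IntegerVector arg, NumericVector dy, IntegerVector xdim) {
  NumericVector dx(xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (int i = 0; i < dy.size(); ++i) dx[arg[i]] += dy[i];
  return dx;
}

// Bilinear upsampling by integer factor k, half-pixel centre alignment.
// [[Rcpp::export(name = ".upsample_fwd")]]
NumericVector upsample_fwd(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H * k, Wo = W * k;
  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> i0(Ho), i1(Ho); std::vector<double> fi(Ho);
  std::vector<int> j0(Wo), j1(Wo); std::vector<double> fj(Wo);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) / k - 0.5;
    if (s < 0) s = 0; if (s > H - 1) s = H - 1;
    i0[i] = (int)std::floor(s); i1[i] = std::min(i0[i] + 1, H - 1); fi[i] = s - i0[i];
  }
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) / k - 0.5;
    if (s < 0) s = 0; if (s > W - 1) s = W - 1;
    j0[j] = (int)std::floor(s); j1[j] = std::min(j0[j] + 1, W - 1); fj[j] = s - j0[j];
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (size_t)H * W * (c + C * n);
      double* ys = y.begin() + (size_t)Ho * Wo * (c + C * n);
      for (int j = 0; j < Wo; ++j) {
        const double* colA = xs + (size_t)H * j0[j];
        const double* colB = xs + (size_t)H * j1[j];
        double* yo = ys + (size_t)Ho * j;
        const double wj = fj[j];
        for (int i = 0; i < Ho; ++i) {
          const double ia = (1 - fi[i]) * colA[i0[i]] + fi[i] * colA[i1[i]];
          const double ib = (1 - fi[i]) * colB[i0[i]] + fi[i] * colB[i1[i]];
          yo[i] = (1 - wj) * ia + wj * ib;
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".upsample_bwd")]]
NumericVector upsample_bwd(NumericVector dy, int k, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H * k, Wo = W * k;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  std::vector<int> i0(Ho), i1(Ho); std::vector<double> fi(Ho);
  std::vector<int> j0(Wo), j1(Wo); std::vector<double> fj(Wo);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) / k - 0.5;
    if (s < 0) s = 0; if (s > H - 1) s = H - 1;
    i0[i] = (int)std::floor(s); i1[i] = std::min(i0[i] + 1, H - 1); fi[i] = s - i0[i];
  }
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) / k - 0.5;
    if (s < 0) s = 0; if (s > W - 1) s = W - 1;
    j0[j] = (int)std::floor(s); j1[j] = std::min(j0[j] + 1, W - 1); fj[j] = s - j0[j];
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xs = dx.begin() + (size_t)H * W * (c + C * n);
      const double* ys = dy.begin() + (size_t)Ho * Wo * (c + C * n);
      for (int j = 0; j < Wo; ++j) {
        double* colA = xs + (size_t)H * j0[j];
        double* colB = xs + (size_t)H * j1[j];
        const double* yo = ys + (size_t)Ho * j;
        const double wj = fj[j];
        for (int i = 0; i < Ho; ++i) {
          const double g = yo[i];
          colA[i0[i]] += (1 - wj) * (1 - fi[i]) * g;
          colA[i1[i]] += (1 - wj) * fi[i] * g;
          colB[i0[i]] += wj * (1 - fi[i]) * g;
          colB[i1[i]] += wj * fi[i] * g;
        }
      }
    }
  return dx;
}

// Batch normalization over (H, W, N) per channel, biased variance.
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta, double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int HW = H * W;
  const double M = (double)HW * N;
  NumericVector mean(C), var(C);
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = xd; xhat.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double s = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + C * n);
      for (int q = 0; q < HW; ++q) s += p[q];
    }
    const double mu = s / M;
    double v = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + C * n);
      for (int q = 0; q < HW; ++q) { const double d = p[q] - mu; v += d * d; }
    }
    v /= M;
    mean[c] = mu; var[c] = v;
    const double inv = 1.0 / std::sqrt(v + eps);
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + C * n);
      double* ph = xhat.begin() + HW * (c + C * n);
      double* py = y.begin() + HW * (c + C * n);
      for (int q = 0; q < HW; ++q) {
        ph[q] = (p[q] - mean[c]) * inv;
        py[q] = gamma[c] * ph[q] + beta[c];
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector dy, NumericVector xhat, NumericVector gamma,
            NumericVector var, double eps) {
  IntegerVector xd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int HW = H * W;
  const double M = (double)HW * N;
  NumericVector dx(dy.size()); dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* pdy = dy.begin() + HW * (c + C * n);
      const double* ph = xhat.begin() + HW * (c + C * n);
      for (int q = 0; q < HW; ++q) { sdy += pdy[q]; sdyx += pdy[q] * ph[q]; }
    }
    dgamma[c] = sdyx; dbeta[c] = sdy;
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double a = gamma[c] * inv / M;
    for (int n = 0; n < N; ++n) {
      const double* pdy = dy.begin() + HW * (c + C * n);
      const double* ph = xhat.begin() + HW * (c + C * n);
      double* pdx = dx.begin() + HW * (c + C * n);
      for (int q = 0; q < HW; ++q)
        pdx[q] = a * (M * pdy[q] - sdy - ph[q] * sdyx);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
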