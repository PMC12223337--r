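// Compiled primitives for the convolutional classifiers and image geometry.
//
// Tensor layout follows R's column-major array convention throughout:
// a batch is an array dim = c(H, W, C, N), i.e. element (h, w, c, n) sits at
// h + H*(w + W*(c + C*n)).  Convolutions are 3x3, stride 1, zero ("same")
// padding, implemented as im2col + one BLAS gemm per image.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Fill the im2col matrix M (9C x H*W) for image n of x.
static void im2col3(const double* x, int H, int W, int C, arma::mat& M) {
  M.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        const int r = (ki + 1) + 3 * (kj + 1) + 9 * c;
        for (int w = 0; w < W; ++w) {
          const int ws = w + kj;
          if (ws < 0 || ws >= W) continue;
          const double* src = xc + (size_t)H * ws;
          double* dst = M.memptr() + (size_t)r + (size_t)M.n_rows * ((size_t)H * w);
          const int h0 = std::max(0, -ki), h1 = std::min(H, H - ki);
          for (int h = h0; h < h1; ++h)
            dst[(size_t)M.n_rows * h] = src[h + ki];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cv_conv3_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != 3 || wd[1] != 3 || wd[2] != C)
    stop("weight array must have dim c(3, 3, C_in, C_out)");
  const int Cout = wd[3];
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);

  arma::mat Wm(const_cast<double*>(w.begin()), 9 * C, Cout, false, true);
  arma::mat M(9 * C, (size_t)H * W);
  const arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);

  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)H * W * C * n, H, W, C, M);
    arma::mat Y(y.begin() + (size_t)H * W * Cout * n, (size_t)H * W, Cout, false, true);
    Y = M.t() * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cv_conv3_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  bool need_dx = true) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  NumericVector dx(x.size());
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dwv(w.size());
  dwv.attr("dim") = wd;
  NumericVector dbv(Cout);

  arma::mat Wm(const_cast<double*>(w.begin()), 9 * C, Cout, false, true);
  arma::mat dW(dwv.begin(), 9 * C, Cout, false, true);
  arma::vec db(dbv.begin(), Cout, false, true);
  arma::mat M(9 * C, (size_t)H * W);
  arma::mat dM(9 * C, (size_t)H * W);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)H * W * Cout * n,
                 (size_t)H * W, Cout, false, true);
    im2col3(xn, H, W, C, M);
    dW += M * dY;
    db += arma::sum(dY, 0).t();
    if (!need_dx) continue;
    dM = Wm * dY.t();
    // col2im: scatter-add back into dx
    double* dxn = dx.begin() + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxn + (size_t)H * W * c;
      for (int kj = -1; kj <= 1; ++kj) {
        for (int ki = -1; ki <= 1; ++ki) {
          const int r = (ki + 1) + 3 * (kj + 1) + 9 * c;
          for (int w2 = 0; w2 < W; ++w2) {
            const int ws = w2 + kj;
            if (ws < 0 || ws >= W) continue;
            double* dst = dxc + (size_t)H * ws;
            const double* src = dM.memptr() + (size_t)r + (size_t)dM.n_rows * ((size_t)H * w2);
            const int h0 = std::max(0, -ki), h1 = std::min(H, H - ki);
            for (int h = h0; h < h1; ++h)
              dst[h + ki] += src[(size_t)dM.n_rows * h];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}

// 2x2 max pooling, stride 2, floor on odd dimensions.  Returns pooled values
// and the 0-based linear index (within the full input array) of each argmax.
// [[Rcpp::export]]
List cv_maxpool2_fwd(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const int Ho = H / 2, Wo = W / 2;
  if (Ho < 1 || Wo < 1) stop("pooling would collapse a spatial dimension to 0");
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector idx(y.size());  // stored as double to hold large indices

  const double* xp = x.begin();
  double* yp = y.begin();
  double* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h, ++o) {
          size_t best = base + (size_t)2 * h + (size_t)H * (2 * w);
          double bv = xp[best];
          const int hh[2] = {2 * h, 2 * h + 1};
          const int ww[2] = {2 * w, 2 * w + 1};
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              const size_t k = base + hh[a] + (size_t)H * ww[b];
              if (xp[k] > bv) { bv = xp[k]; best = k; }
            }
          yp[o] = bv;
          ip[o] = (double)best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cv_maxpool2_bwd(NumericVector dy, NumericVector idx, IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  const double* dyp = dy.begin();
  const double* ip = idx.begin();
  double* dxp = dx.begin();
  const size_t n = dy.size();
  for (size_t i = 0; i < n; ++i) dxp[(size_t)ip[i]] += dyp[i];
  return dx;
}

// k x k average pooling, stride k, floor on remainder dimensions.
// [[Rcpp::export]]
NumericVector cv_avgpool_fwd(NumericVector x, int k) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const int Ho = H / k, Wo = W / k;
  if (Ho < 1 || Wo < 1) stop("pooling would collapse a spatial dimension to 0");
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  size_t o = 0;
  const double inv = 1.0 / ((double)k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          double s = 0;
          for (int b = 0; b < k; ++b)
            for (int a = 0; a < k; ++a)
              s += xp[base + (k * h + a) + (size_t)H * (k * w + b)];
          yp[o] = s * inv;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cv_avgpool_bwd(NumericVector dy, int k, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / k, Wo = W / k;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  size_t o = 0;
  const double inv = 1.0 / ((double)k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          const double g = dyp[o] * inv;
          for (int b = 0; b < k; ++b)
            for (int a = 0; a < k; ++a)
              dxp[base + (k * h + a) + (size_t)H * (k * w + b)] += g;
        }
    }
  return dx;
}

// Batch normalization over (H, W, N) per channel.  Training mode computes
// batch statistics (biased variance) and updates running statistics with the
// given momentum (running <- (1 - momentum) * running + momentum * batch).
// When `relu` is true the activation is fused: y = max(0, gamma*xhat + beta).
// [[Rcpp::export]]
List cv_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
               NumericVector rmean, NumericVector rvar,
               double momentum, double eps, bool training, bool relu = false) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  NumericVector xhat(training ? x.size() : 0);
  if (training) xhat.attr("dim") = x.attr("dim");
  NumericVector invstd(C), nrmean = clone(rmean), nrvar = clone(rvar);
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;

  for (int c = 0; c < C; ++c) {
    double mu, var;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + plane * (c + (size_t)C * n);
        for (size_t i = 0; i < plane; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      }
      mu = s / m;
      var = s2 / m - mu * mu;
      if (var < 0) var = 0;
      const double unb = m > 1 ? var * m / (m - 1) : var;
      nrmean[c] = (1 - momentum) * nrmean[c] + momentum * mu;
      nrvar[c]  = (1 - momentum) * nrvar[c]  + momentum * unb;
    } else {
      mu = rmean[c]; var = rvar[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* xc = x.begin() + off;
      double* yc = y.begin() + off;
      if (training) {
        double* hc = xhat.begin() + off;
        if (relu) {
          for (size_t i = 0; i < plane; ++i) {
            hc[i] = (xc[i] - mu) * is;
            const double v = g * hc[i] + b;
            yc[i] = v > 0 ? v : 0;
          }
        } else {
          for (size_t i = 0; i < plane; ++i) {
            hc[i] = (xc[i] - mu) * is;
            yc[i] = g * hc[i] + b;
          }
        }
      } else {
        if (relu) {
          for (size_t i = 0; i < plane; ++i) {
            const double v = g * (xc[i] - mu) * is + b;
            yc[i] = v > 0 ? v : 0;
          }
        } else {
          for (size_t i = 0; i < plane; ++i)
            yc[i] = g * (xc[i] - mu) * is + b;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["rmean"] = nrmean, _["rvar"] = nrvar);
}

// [[Rcpp::export]]
List cv_bn_bwd(NumericVector dy, NumericVector xhat, NumericVector gamma,
               NumericVector invstd) {
  int H, W, C, N; get_dims4(dy, H, W, C, N);
  NumericVector dx(dy.size()); dx.attr("dim") = dy.attr("dim");
  NumericVector dgamma(C), dbeta(C);
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;
  for (int c = 0; c < C; ++c) {
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* d = dy.begin() + off;
      const double* h = xhat.begin() + off;
      for (size_t i = 0; i < plane; ++i) { sdy += d[i]; sdyx += d[i] * h[i]; }
    }
    dgamma[c] = sdyx; dbeta[c] = sdy;
    const double k = gamma[c] * invstd[c] / m;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* d = dy.begin() + off;
      const double* h = xhat.begin() + off;
      double* o = dx.begin() + off;
      for (size_t i = 0; i < plane; ++i)
        o[i] = k * (m * d[i] - sdy - h[i] * sdyx);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Backward through fused batchnorm+ReLU (training forward with relu = true).
// The ReLU mask is reconstructed from xhat: active iff gamma*xhat + beta > 0.
// [[Rcpp::export]]
List cv_bn_relu_bwd(NumericVector dy, NumericVector xhat, NumericVector gamma,
                    NumericVector beta, NumericVector invstd) {
  int H, W, C, N; get_dims4(dy, H, W, C, N);
  NumericVector dx(dy.size()); dx.attr("dim") = dy.attr("dim");
  NumericVector dgamma(C), dbeta(C);
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;
  std::vector<double> masked(plane * (size_t)N);
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], b = beta[c];
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* d = dy.begin() + off;
      const double* h = xhat.begin() + off;
      double* mk = masked.data() + plane * n;
      for (size_t i = 0; i < plane; ++i) {
        const double v = (g * h[i] + b > 0) ? d[i] : 0.0;
        mk[i] = v;
        sdy += v; sdyx += v * h[i];
      }
    }
    dgamma[c] = sdyx; dbeta[c] = sdy;
    const double k = g * invstd[c] / m;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* h = xhat.begin() + off;
      const double* mk = masked.data() + plane * n;
      double* o = dx.begin() + off;
      for (size_t i = 0; i < plane; ++i)
        o[i] = k * (m * mk[i] - sdy - h[i] * sdyx);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// One fused Adam update; returns the new parameter and moment vectors.
// [[Rcpp::export]]
List cv_adam_step(NumericVector p, NumericVector g, NumericVector m,
                  NumericVector v, double lr, double beta1, double beta2,
                  double eps, int t) {
  const R_xlen_t n = p.size();
  NumericVector np(no_init(n)), nm(no_init(n)), nv(no_init(n));
  const double c1 = 1.0 - std::pow(beta1, t), c2 = 1.0 - std::pow(beta2, t);
  double* pp = np.begin(); double* pm = nm.begin(); double* pv = nv.begin();
  const double* pg = g.begin(); const double* p0 = p.begin();
  const double* m0 = m.begin(); const double* v0 = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = beta1 * m0[i] + (1 - beta1) * pg[i];
    pv[i] = beta2 * v0[i] + (1 - beta2) * pg[i] * pg[i];
    pp[i] = p0[i] - lr * (pm[i] / c1) / (std::sqrt(pv[i] / c2) + eps);
  }
  np.attr("dim") = p.attr("dim");
  return List::create(_["p"] = np, _["m"] = nm, _["v"] = nv);
}

// ---- image geometry -------------------------------------------------------

// Catmull-Rom cubic convolution kernel (a = -0.5), the common "bicubic".
static inline double cubic_w(double t) {
  const double a = -0.5;
  t = std::fabs(t);
  if (t <= 1.0) return ((a + 2.0) * t - (a + 3.0)) * t * t + 1.0;
  if (t < 2.0)  return (((t - 5.0) * t + 8.0) * t - 4.0) * a;
  return 0.0;
}

// Bicubic resample of an (H, W, C) image to (out_h, out_w), edge-clamped,
// pixel-center aligned.
// [[Rcpp::export]]
NumericVector cv_resize_bicubic(NumericVector img, int out_h, int out_w) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3) stop("expected an (H, W, C) array");
  const int H = d[0], W = d[1], C = d[2];
  if (out_h < 1 || out_w < 1) stop("output size must be positive");
  NumericVector out((size_t)out_h * out_w * C);
  out.attr("dim") = IntegerVector::create(out_h, out_w, C);

  const double sy = (double)H / out_h, sx = (double)W / out_w;
  std::vector<int> ix0(out_w); std::vector<double> wx(4 * out_w);
  for (int j = 0; j < out_w; ++j) {
    const double src = (j + 0.5) * sx - 0.5;
    const int j0 = (int)std::floor(src) - 1;
    ix0[j] = j0;
    for (int k = 0; k < 4; ++k) wx[4 * j + k] = cubic_w(src - (j0 + k));
  }
  std::vector<int> iy0(out_h); std::vector<double> wy(4 * out_h);
  for (int i = 0; i < out_h; ++i) {
    const double src = (i + 0.5) * sy - 0.5;
    const int i0 = (int)std::floor(src) - 1;
    iy0[i] = i0;
    for (int k = 0; k < 4; ++k) wy[4 * i + k] = cubic_w(src - (i0 + k));
  }
  for (int c = 0; c < C; ++c) {
    const double* src = img.begin() + (size_t)H * W * c;
    double* dst = out.begin() + (size_t)out_h * out_w * c;
    for (int j = 0; j < out_w; ++j) {
      int jc[4];
      for (int k = 0; k < 4; ++k)
        jc[k] = std::min(W - 1, std::max(0, ix0[j] + k));
      for (int i = 0; i < out_h; ++i) {
        double acc = 0, wsum = 0;
        for (int b = 0; b < 4; ++b) {
          const double wwx = wx[4 * j + b];
          const double* col = src + (size_t)H * jc[b];
          for (int a = 0; a < 4; ++a) {
            const int ii = std::min(H - 1, std::max(0, iy0[i] + a));
            const double wt = wy[4 * i + a] * wwx;
            acc += wt * col[ii]; wsum += wt;
          }
        }
        dst[i + (size_t)out_h * j] = acc / wsum;
      }
    }
  }
  return out;
}

// Inverse-mapped affine warp with bilinear sampling and edge clamping.
// A is the 2x2 output->input linear map about the image center, t an extra
// translation (in input pixels, (dx, dy)).
// [[Rcpp::export]]
NumericVector cv_affine_bilinear(NumericVector img, NumericMatrix A, NumericVector t) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  NumericVector out(img.size());
  out.attr("dim") = d;
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double xo = j - cx, yo = i - cy;
      double xs = A(0, 0) * xo + A(0, 1) * yo + cx + t[0];
      double ys = A(1, 0) * xo + A(1, 1) * yo + cy + t[1];
      xs = std::min((double)W - 1, std::max(0.0, xs));
      ys = std::min((double)H - 1, std::max(0.0, ys));
      const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      const int x1 = std::min(W - 1, x0 + 1), y1 = std::min(H - 1, y0 + 1);
      const double fx = xs - x0, fy = ys - y0;
      for (int c = 0; c < C; ++c) {
        const double* src = img.begin() + (size_t)H * W * c;
        const double v =
          (1 - fy) * ((1 - fx) * src[y0 + (size_t)H * x0] + fx * src[y0 + (size_t)H * x1]) +
          fy       * ((1 - fx) * src[y1 + (size_t)H * x0] + fx * src[y1 + (size_t)H * x1]);
        out[i + (size_t)H * j + (size_t)H * W * c] = v;
      }
    }
  }
  return out;
}

// Separable Gaussian blur of a single-channel matrix, kernel truncated at 3 sigma.
// [[Rcpp::export]]
NumericMatrix cv_gauss_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (auto& v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int a = -r; a <= r; ++a) {
        int ii = std::min(H - 1, std::max(0, i + a));
        acc += k[a + r] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int a = -r; a <= r; ++a) {
        int jj = std::min(W - 1, std::max(0, j + a));
        acc += k[a + r] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}
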