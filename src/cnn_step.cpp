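// Single-precision training engine for the 4-block basic CNN.
//
// Two entry points share one forward/backward core:
//  * cv_cnn4_step()  — stateless: takes R parameters, returns loss + grads
//    (used to cross-check the layered double-precision reference path);
//  * cnn4_trainer_*  — a persistent trainer holding parameters, Adam
//    moments and batch-norm running statistics in C++, so a training step
//    costs one R call with no large allocations on the R heap.

#include <RcppArmadillo.h>
using namespace Rcpp;

template <typename T>
static void im2col3f(const T* x, int H, int W, int C, arma::fmat& M) {
  M.zeros();
  for (int c = 0; c < C; ++c) {
    const T* xc = x + (size_t)H * W * c;
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        const int r = (ki + 1) + 3 * (kj + 1) + 9 * c;
        for (int w = 0; w < W; ++w) {
          const int ws = w + kj;
          if (ws < 0 || ws >= W) continue;
          const T* src = xc + (size_t)H * ws;
          float* dst = M.memptr() + (size_t)r + (size_t)M.n_rows * ((size_t)H * w);
          const int h0 = std::max(0, -ki), h1 = std::min(H, H - ki);
          for (int h = h0; h < h1; ++h)
            dst[(size_t)M.n_rows * h] = (float)src[h + ki];
        }
      }
    }
  }
}

static void col2imf(const arma::fmat& dM, int H, int W, int C, float* dx) {
  for (int c = 0; c < C; ++c) {
    float* dxc = dx + (size_t)H * W * c;
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        const int r = (ki + 1) + 3 * (kj + 1) + 9 * c;
        for (int w = 0; w < W; ++w) {
          const int ws = w + kj;
          if (ws < 0 || ws >= W) continue;
          float* dst = dxc + (size_t)H * ws;
          const float* src = dM.memptr() + (size_t)r + (size_t)dM.n_rows * ((size_t)H * w);
          const int h0 = std::max(0, -ki), h1 = std::min(H, H - ki);
          for (int h = h0; h < h1; ++h)
            dst[h + ki] += src[(size_t)dM.n_rows * h];
        }
      }
    }
  }
}

struct ConvPar {
  int cin = 0, cout = 0;
  arma::fmat W;                 // 9*cin x cout
  arma::fvec b, gamma, beta;
  arma::fvec rmean, rvar;       // running stats
};
struct FcPar {
  arma::fmat W;
  arma::fvec b;
};

struct Net {
  std::vector<ConvPar> conv;    // 4 blocks
  std::vector<FcPar> fc;        // 3 layers
};

struct ConvGrad {
  arma::fmat W;
  arma::fvec b, gamma, beta;
  arma::fvec bmean, bvar;       // batch stats of this step
};
struct FcGrad {
  arma::fmat W;
  arma::fvec b;
};
struct Grads {
  std::vector<ConvGrad> conv;
  std::vector<FcGrad> fc;
};

static Net net_from_r(List params) {
  Net net;
  net.conv.resize(4);
  for (int l = 0; l < 4; ++l) {
    List p = params[std::string("conv") + std::to_string(l + 1)];
    NumericVector wv = p["w"];
    IntegerVector wd = wv.attr("dim");
    ConvPar& c = net.conv[l];
    c.cin = wd[2]; c.cout = wd[3];
    c.W.set_size(9 * c.cin, c.cout);
    std::copy(wv.begin(), wv.end(), c.W.begin());
    c.b = arma::conv_to<arma::fvec>::from(as<arma::vec>(as<NumericVector>(p["b"])));
    c.gamma = arma::conv_to<arma::fvec>::from(as<arma::vec>(as<NumericVector>(p["gamma"])));
    c.beta = arma::conv_to<arma::fvec>::from(as<arma::vec>(as<NumericVector>(p["beta"])));
    c.rmean = arma::conv_to<arma::fvec>::from(as<arma::vec>(as<NumericVector>(p["rmean"])));
    c.rvar = arma::conv_to<arma::fvec>::from(as<arma::vec>(as<NumericVector>(p["rvar"])));
  }
  net.fc.resize(3);
  for (int l = 0; l < 3; ++l) {
    List p = params[std::string("fc") + std::to_string(l + 1)];
    NumericMatrix wv = p["w"];
    net.fc[l].W.set_size(wv.nrow(), wv.ncol());
    std::copy(wv.begin(), wv.end(), net.fc[l].W.begin());
    net.fc[l].b = arma::conv_to<arma::fvec>::from(as<arma::vec>(
      as<NumericVector>(p["b"])));
  }
  return net;
}

// One forward+backward pass.  Fills `g` and returns (loss, probs).
static double net_step(const Net& net, NumericVector x, IntegerVector labels,
                       NumericVector class_w, List drop_masks, double bn_eps,
                       Grads& g, NumericMatrix& probs_out) {
  IntegerVector xd = x.attr("dim");
  const int H0 = xd[0], W0 = xd[1], C0 = xd[2], N = xd[3];

  struct Act {
    int Hin, Win, Hout, Wout;
    std::vector<float> xhat;  // pre-pool
    std::vector<float> act;   // pooled relu output
    std::vector<int> idx;
    arma::fvec mean, invstd;
  };
  std::vector<Act> A(4);

  std::vector<float> a0((size_t)H0 * W0 * C0 * N);
  for (size_t i = 0; i < a0.size(); ++i) a0[i] = (float)x[i];

  const float* cur = a0.data();
  int h = H0, w = W0;
  for (int l = 0; l < 4; ++l) {
    const ConvPar& cp = net.conv[l];
    Act& al = A[l];
    al.Hin = h; al.Win = w;
    al.Hout = h / 2; al.Wout = w / 2;
    if (al.Hout < 1 || al.Wout < 1) stop("pooling collapses a spatial dimension");
    const size_t plane = (size_t)h * w, oplane = (size_t)al.Hout * al.Wout;
    al.xhat.assign(plane * cp.cout * N, 0.f);
    al.act.assign(oplane * cp.cout * N, 0.f);
    al.idx.assign(oplane * cp.cout * N, 0);
    arma::fmat M(9 * cp.cin, plane);
    for (int n = 0; n < N; ++n) {
      im2col3f(cur + plane * cp.cin * n, h, w, cp.cin, M);
      arma::fmat Z(al.xhat.data() + plane * cp.cout * n, plane, cp.cout,
                   false, true);
      Z = M.t() * cp.W;
      Z.each_row() += cp.b.t();
    }
    al.mean.set_size(cp.cout); al.invstd.set_size(cp.cout);
    const double m = (double)plane * N;
    for (int c = 0; c < cp.cout; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const float* z = al.xhat.data() + plane * (c + (size_t)cp.cout * n);
        for (size_t i = 0; i < plane; ++i) { s += z[i]; s2 += (double)z[i] * z[i]; }
      }
      const double mu = s / m;
      double var = s2 / m - mu * mu;
      if (var < 0) var = 0;
      al.mean[c] = (float)mu;
      al.invstd[c] = (float)(1.0 / std::sqrt(var + bn_eps));
    }
    for (int c = 0; c < cp.cout; ++c) {
      const float mu = al.mean[c], is = al.invstd[c];
      const float ga = cp.gamma[c], be = cp.beta[c];
      for (int n = 0; n < N; ++n) {
        float* z = al.xhat.data() + plane * (c + (size_t)cp.cout * n);
        for (size_t i = 0; i < plane; ++i) z[i] = (z[i] - mu) * is;
        float* out = al.act.data() + oplane * (c + (size_t)cp.cout * n);
        int* oid = al.idx.data() + oplane * (c + (size_t)cp.cout * n);
        for (int ww = 0; ww < al.Wout; ++ww) {
          for (int hh = 0; hh < al.Hout; ++hh) {
            float best = -1.f; int besti = 2 * hh + al.Hin * (2 * ww);
            for (int b2 = 0; b2 < 2; ++b2)
              for (int a2 = 0; a2 < 2; ++a2) {
                const int ii = 2 * hh + a2 + al.Hin * (2 * ww + b2);
                const float v = ga * z[ii] + be;
                const float rv = v > 0 ? v : 0.f;
                if (rv > best) { best = rv; besti = ii; }
              }
            out[hh + (size_t)al.Hout * ww] = best;
            oid[hh + (size_t)al.Hout * ww] = besti;
          }
        }
      }
    }
    cur = al.act.data();
    h = al.Hout; w = al.Wout;
  }

  const size_t D = (size_t)h * w * net.conv[3].cout;
  arma::fmat A0f(const_cast<float*>(cur), D, N, false, true);

  arma::fmat dm[2];
  for (int l = 0; l < 2; ++l) {
    NumericMatrix mk = drop_masks[l];
    if (mk.nrow() > 0) {
      dm[l].set_size(mk.nrow(), mk.ncol());
      std::copy(mk.begin(), mk.end(), dm[l].begin());
    }
  }
  arma::fmat A1 = net.fc[0].W.t() * A0f; A1.each_col() += net.fc[0].b;
  if (dm[0].n_rows) A1 %= dm[0];
  arma::fmat R1 = arma::clamp(A1, 0.f, std::numeric_limits<float>::max());
  arma::fmat A2 = net.fc[1].W.t() * R1; A2.each_col() += net.fc[1].b;
  if (dm[1].n_rows) A2 %= dm[1];
  arma::fmat R2 = arma::clamp(A2, 0.f, std::numeric_limits<float>::max());
  arma::fmat Z3 = net.fc[2].W.t() * R2; Z3.each_col() += net.fc[2].b;

  const int K = Z3.n_rows;
  probs_out = NumericMatrix(N, K);
  arma::fmat dZ3(K, N);
  double loss = 0, wsum = 0;
  std::vector<double> wvec(N);
  for (int n = 0; n < N; ++n) { wvec[n] = class_w[labels[n] - 1]; wsum += wvec[n]; }
  const double wmean = wsum / N;
  for (int n = 0; n < N; ++n) {
    double mx = Z3(0, n);
    for (int k = 1; k < K; ++k) mx = std::max(mx, (double)Z3(k, n));
    double se = 0;
    for (int k = 0; k < K; ++k) se += std::exp((double)Z3(k, n) - mx);
    const double wn = wvec[n] / wmean;
    for (int k = 0; k < K; ++k) {
      const double p = std::exp((double)Z3(k, n) - mx) / se;
      probs_out(n, k) = p;
      dZ3(k, n) = (float)((p - (labels[n] - 1 == k ? 1.0 : 0.0)) * wn / N);
    }
    loss -= wn * std::log(std::max(probs_out(n, labels[n] - 1), 1e-12));
  }
  loss /= N;

  // ---- backward ----
  g.fc.resize(3); g.conv.resize(4);
  g.fc[2].W = R2 * dZ3.t();
  g.fc[2].b = arma::sum(dZ3, 1);
  arma::fmat dR2 = net.fc[2].W * dZ3;
  dR2 %= arma::conv_to<arma::fmat>::from(A2 > 0);
  if (dm[1].n_rows) dR2 %= dm[1];
  g.fc[1].W = R1 * dR2.t();
  g.fc[1].b = arma::sum(dR2, 1);
  arma::fmat dR1 = net.fc[1].W * dR2;
  dR1 %= arma::conv_to<arma::fmat>::from(A1 > 0);
  if (dm[0].n_rows) dR1 %= dm[0];
  g.fc[0].W = A0f * dR1.t();
  g.fc[0].b = arma::sum(dR1, 1);
  arma::fmat dA0 = net.fc[0].W * dR1;

  std::vector<float> da(dA0.begin(), dA0.end());
  for (int l = 3; l >= 0; --l) {
    const ConvPar& cp = net.conv[l];
    Act& al = A[l];
    const size_t plane = (size_t)al.Hin * al.Win;
    const size_t oplane = (size_t)al.Hout * al.Wout;
    std::vector<float> dz(plane * cp.cout * N, 0.f);
    ConvGrad& cg = g.conv[l];
    cg.gamma.set_size(cp.cout); cg.beta.set_size(cp.cout);
    cg.bmean.set_size(cp.cout); cg.bvar.set_size(cp.cout);
    const double m = (double)plane * N;
    for (int c = 0; c < cp.cout; ++c) {
      const float ga = cp.gamma[c], be = cp.beta[c], is = al.invstd[c];
      double sdy = 0, sdyx = 0;
      for (int n = 0; n < N; ++n) {
        const float* dap = da.data() + oplane * (c + (size_t)cp.cout * n);
        const int* oid = al.idx.data() + oplane * (c + (size_t)cp.cout * n);
        const float* xh = al.xhat.data() + plane * (c + (size_t)cp.cout * n);
        float* dzp = dz.data() + plane * (c + (size_t)cp.cout * n);
        for (size_t i = 0; i < oplane; ++i) {
          const int ii = oid[i];
          if (ga * xh[ii] + be > 0) dzp[ii] += dap[i];
        }
        for (size_t i = 0; i < plane; ++i) {
          sdy += dzp[i]; sdyx += (double)dzp[i] * xh[i];
        }
      }
      cg.gamma[c] = (float)sdyx; cg.beta[c] = (float)sdy;
      cg.bmean[c] = al.mean[c];
      const double var = 1.0 / ((double)al.invstd[c] * al.invstd[c]) - bn_eps;
      cg.bvar[c] = (float)(m > 1 ? var * m / (m - 1) : var);
      const float k = (float)((double)ga * is / m);
      const float msdy = (float)sdy, msdyx = (float)sdyx;
      for (int n = 0; n < N; ++n) {
        const float* xh = al.xhat.data() + plane * (c + (size_t)cp.cout * n);
        float* dzp = dz.data() + plane * (c + (size_t)cp.cout * n);
        for (size_t i = 0; i < plane; ++i)
          dzp[i] = k * ((float)m * dzp[i] - msdy - xh[i] * msdyx);
      }
    }
    const float* below = (l == 0) ? a0.data() : A[l - 1].act.data();
    arma::fmat M(9 * cp.cin, plane);
    cg.W.zeros(9 * cp.cin, cp.cout);
    cg.b.zeros(cp.cout);
    std::vector<float> dbelow;
    if (l > 0) dbelow.assign(plane * cp.cin * N, 0.f);
    for (int n = 0; n < N; ++n) {
      arma::fmat dZm(dz.data() + plane * cp.cout * n, plane, cp.cout, false, true);
      im2col3f(below + plane * cp.cin * n, al.Hin, al.Win, cp.cin, M);
      cg.W += M * dZm;
      cg.b += arma::sum(dZm, 0).t();
      if (l > 0) {
        arma::fmat dM = cp.W * dZm.t();
        col2imf(dM, al.Hin, al.Win, cp.cin, dbelow.data() + plane * cp.cin * n);
      }
    }
    da.swap(dbelow);
  }
  return loss;
}

// ---- stateless step (cross-check interface) -------------------------------

// [[Rcpp::export]]
List cv_cnn4_step(List params, NumericVector x, IntegerVector labels,
                  NumericVector class_w, List drop_masks, double bn_momentum,
                  double bn_eps) {
  (void)bn_momentum;
  Net net = net_from_r(params);
  Grads g;
  NumericMatrix probs;
  const double loss = net_step(net, x, labels, class_w, drop_masks, bn_eps,
                               g, probs);
  List conv_g(4), bn_s(4), fc_g(3);
  CharacterVector conv_names(4), fc_names(3);
  for (int l = 0; l < 4; ++l) {
    NumericVector gw((R_xlen_t)g.conv[l].W.n_elem);
    std::copy(g.conv[l].W.begin(), g.conv[l].W.end(), gw.begin());
    gw.attr("dim") = IntegerVector::create(3, 3, net.conv[l].cin,
                                           net.conv[l].cout);
    conv_g[l] = List::create(
      _["w"] = gw, _["b"] = NumericVector(g.conv[l].b.begin(), g.conv[l].b.end()),
      _["gamma"] = NumericVector(g.conv[l].gamma.begin(), g.conv[l].gamma.end()),
      _["beta"] = NumericVector(g.conv[l].beta.begin(), g.conv[l].beta.end()));
    bn_s[l] = List::create(
      _["mean"] = NumericVector(g.conv[l].bmean.begin(), g.conv[l].bmean.end()),
      _["var"] = NumericVector(g.conv[l].bvar.begin(), g.conv[l].bvar.end()));
    conv_names[l] = "conv" + std::to_string(l + 1);
  }
  for (int l = 0; l < 3; ++l) {
    NumericMatrix gw(g.fc[l].W.n_rows, g.fc[l].W.n_cols);
    std::copy(g.fc[l].W.begin(), g.fc[l].W.end(), gw.begin());
    fc_g[l] = List::create(
      _["w"] = gw, _["b"] = NumericVector(g.fc[l].b.begin(), g.fc[l].b.end()));
    fc_names[l] = "fc" + std::to_string(l + 1);
  }
  conv_g.attr("names") = conv_names;
  bn_s.attr("names") = conv_names;
  fc_g.attr("names") = fc_names;
  List grads;
  {
    List all(7);
    CharacterVector nm(7);
    for (int l = 0; l < 4; ++l) { all[l] = conv_g[l]; nm[l] = conv_names[l]; }
    for (int l = 0; l < 3; ++l) { all[4 + l] = fc_g[l]; nm[4 + l] = fc_names[l]; }
    all.attr("names") = nm;
    grads = all;
  }
  return List::create(_["loss"] = loss, _["probs"] = probs,
                      _["grads"] = grads, _["bn_stats"] = bn_s);
}

// ---- persistent trainer ---------------------------------------------------

struct AdamState {
  arma::fmat mW, vW;
  arma::fvec mb, vb, mg, vg, mbe, vbe;
};

struct Trainer {
  Net net;
  std::vector<AdamState> conv_opt;  // per conv layer
  std::vector<AdamState> fc_opt;    // per fc layer (only W/b used)
  int t = 0;
  double bn_momentum, bn_eps;
};

static void adamf(arma::fmat& p, const arma::fmat& g, arma::fmat& m,
                  arma::fmat& v, float lr, int t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  const float c1 = 1.f - std::pow(b1, (float)t);
  const float c2 = 1.f - std::pow(b2, (float)t);
  float* pp = p.memptr(); float* pm = m.memptr(); float* pv = v.memptr();
  const float* pg = g.memptr();
  const size_t n = p.n_elem;
  for (size_t i = 0; i < n; ++i) {
    pm[i] = b1 * pm[i] + (1 - b1) * pg[i];
    pv[i] = b2 * pv[i] + (1 - b2) * pg[i] * pg[i];
    pp[i] -= lr * (pm[i] / c1) / (std::sqrt(pv[i] / c2) + eps);
  }
}
static void adamv(arma::fvec& p, const arma::fvec& g, arma::fvec& m,
                  arma::fvec& v, float lr, int t) {
  arma::fmat pm(p.memptr(), p.n_elem, 1, false, true);
  arma::fmat gm(const_cast<float*>(g.memptr()), g.n_elem, 1, false, true);
  arma::fmat mm(m.memptr(), m.n_elem, 1, false, true);
  arma::fmat vm(v.memptr(), v.n_elem, 1, false, true);
  adamf(pm, gm, mm, vm, lr, t);
}

// [[Rcpp::export]]
SEXP cnn4_trainer_new(List params, double bn_momentum = 0.1,
                      double bn_eps = 1e-5) {
  Trainer* tr = new Trainer();
  tr->net = net_from_r(params);
  tr->bn_momentum = bn_momentum;
  tr->bn_eps = bn_eps;
  tr->conv_opt.resize(4);
  for (int l = 0; l < 4; ++l) {
    ConvPar& c = tr->net.conv[l];
    AdamState& s = tr->conv_opt[l];
    s.mW.zeros(c.W.n_rows, c.W.n_cols); s.vW.zeros(c.W.n_rows, c.W.n_cols);
    s.mb.zeros(c.b.n_elem); s.vb.zeros(c.b.n_elem);
    s.mg.zeros(c.gamma.n_elem); s.vg.zeros(c.gamma.n_elem);
    s.mbe.zeros(c.beta.n_elem); s.vbe.zeros(c.beta.n_elem);
  }
  tr->fc_opt.resize(3);
  for (int l = 0; l < 3; ++l) {
    FcPar& f = tr->net.fc[l];
    AdamState& s = tr->fc_opt[l];
    s.mW.zeros(f.W.n_rows, f.W.n_cols); s.vW.zeros(f.W.n_rows, f.W.n_cols);
    s.mb.zeros(f.b.n_elem); s.vb.zeros(f.b.n_elem);
  }
  XPtr<Trainer> ptr(tr, true);
  return ptr;
}

// [[Rcpp::export]]
double cnn4_trainer_step(SEXP trainer, NumericVector x, IntegerVector labels,
                         NumericVector class_w, List drop_masks, double lr,
                         double grad_clip = 0) {
  XPtr<Trainer> tr(trainer);
  Grads g;
  NumericMatrix probs;
  const double loss = net_step(tr->net, x, labels, class_w, drop_masks,
                               tr->bn_eps, g, probs);
  if (grad_clip > 0) {
    // clip by global L2 norm across every gradient tensor
    double ss = 0;
    for (int l = 0; l < 4; ++l) {
      ss += arma::dot(g.conv[l].W, g.conv[l].W) +
        arma::dot(g.conv[l].b, g.conv[l].b) +
        arma::dot(g.conv[l].gamma, g.conv[l].gamma) +
        arma::dot(g.conv[l].beta, g.conv[l].beta);
    }
    for (int l = 0; l < 3; ++l) {
      ss += arma::dot(g.fc[l].W, g.fc[l].W) + arma::dot(g.fc[l].b, g.fc[l].b);
    }
    const double norm = std::sqrt(ss);
    if (norm > grad_clip) {
      const float sc = (float)(grad_clip / norm);
      for (int l = 0; l < 4; ++l) {
        g.conv[l].W *= sc; g.conv[l].b *= sc;
        g.conv[l].gamma *= sc; g.conv[l].beta *= sc;
      }
      for (int l = 0; l < 3; ++l) { g.fc[l].W *= sc; g.fc[l].b *= sc; }
    }
  }
  tr->t += 1;
  for (int l = 0; l < 4; ++l) {
    ConvPar& c = tr->net.conv[l];
    AdamState& s = tr->conv_opt[l];
    adamf(c.W, g.conv[l].W, s.mW, s.vW, (float)lr, tr->t);
    adamv(c.b, g.conv[l].b, s.mb, s.vb, (float)lr, tr->t);
    adamv(c.gamma, g.conv[l].gamma, s.mg, s.vg, (float)lr, tr->t);
    adamv(c.beta, g.conv[l].beta, s.mbe, s.vbe, (float)lr, tr->t);
    const float mom = (float)tr->bn_momentum;
    c.rmean = (1 - mom) * c.rmean + mom * g.conv[l].bmean;
    c.rvar = (1 - mom) * c.rvar + mom * g.conv[l].bvar;
  }
  for (int l = 0; l < 3; ++l) {
    FcPar& f = tr->net.fc[l];
    AdamState& s = tr->fc_opt[l];
    adamf(f.W, g.fc[l].W, s.mW, s.vW, (float)lr, tr->t);
    adamv(f.b, g.fc[l].b, s.mb, s.vb, (float)lr, tr->t);
  }
  return loss;
}

// Export the trainer's parameters as an R list shaped like model$params.
// [[Rcpp::export]]
List cnn4_trainer_export(SEXP trainer) {
  XPtr<Trainer> tr(trainer);
  List out(7);
  CharacterVector nm(7);
  for (int l = 0; l < 4; ++l) {
    const ConvPar& c = tr->net.conv[l];
    NumericVector w((R_xlen_t)c.W.n_elem);
    std::copy(c.W.begin(), c.W.end(), w.begin());
    w.attr("dim") = IntegerVector::create(3, 3, c.cin, c.cout);
    out[l] = List::create(
      _["w"] = w,
      _["b"] = NumericVector(c.b.begin(), c.b.end()),
      _["gamma"] = NumericVector(c.gamma.begin(), c.gamma.end()),
      _["beta"] = NumericVector(c.beta.begin(), c.beta.end()),
      _["rmean"] = NumericVector(c.rmean.begin(), c.rmean.end()),
      _["rvar"] = NumericVector(c.rvar.begin(), c.rvar.end()));
    nm[l] = "conv" + std::to_string(l + 1);
  }
  for (int l = 0; l < 3; ++l) {
    const FcPar& f = tr->net.fc[l];
    NumericMatrix w(f.W.n_rows, f.W.n_cols);
    std::copy(f.W.begin(), f.W.end(), w.begin());
    out[4 + l] = List::create(
      _["w"] = w, _["b"] = NumericVector(f.b.begin(), f.b.end()));
    nm[4 + l] = "fc" + std::to_string(l + 1);
  }
  out.attr("names") = nm;
  return out;
}
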