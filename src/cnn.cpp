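// Compact reference CNN for 180x180 single-channel scattering images.
//
// Architecture (fixed): 4 blocks of [3x3 convolution, stride 2, pad 1 ->
// batch norm -> ReLU] with 16/32/64/128 channels (the stride-2 convolution
// performs the downsampling), global average pooling, and a C-way fully
// connected output trained with softmax cross-entropy and Adam.
//
// Single-precision arithmetic. Convolutions run via im2col + one BLAS GEMM
// per layer over a sub-batch of images at a time (columns of the im2col
// matrix are grouped per image), which keeps the GEMMs large enough to be
// efficient on a single CPU core. Weight init and mini-batch shuffling use
// the R RNG, so results are reproducible under set.seed().

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uword;

static const int NBLK = 4;
static const int CH[NBLK + 1] = {1, 16, 32, 64, 128};
static const int IMG = 180;
static const int SUB = 16;   // images per GEMM group

struct Dims { int H, W, Ho, Wo; };

// output size of a 3x3, stride-2, pad-1 convolution
static inline int out_sz(int n) { return (n - 1) / 2 + 1; }

static std::vector<Dims> layer_dims() {
  std::vector<Dims> d(NBLK);
  int h = IMG, w = IMG;
  for (int l = 0; l < NBLK; ++l) {
    d[l].H = h; d[l].W = w;
    d[l].Ho = out_sz(h); d[l].Wo = out_sz(w);
    h = d[l].Ho; w = d[l].Wo;
  }
  return d;
}

// x: Cin x (H*W*B) activations, images stacked along columns.
// cols: (9*Cin) x (Ho*Wo*B), row index k*Cin + c (channel-contiguous per
// kernel offset); output position (io, jo) reads input (2io+di, 2jo+dj).
static void im2col(const fmat& x, int H, int W, int B, fmat& cols) {
  int Cin = x.n_rows, Ho = out_sz(H), Wo = out_sz(W);
  cols.zeros(9 * Cin, (size_t)Ho * Wo * B);
  const size_t Crow = 9 * (size_t)Cin;
  for (int b = 0; b < B; ++b) {
    const float* xb = x.memptr() + (size_t)Cin * H * W * b;
    float* cb = cols.memptr() + Crow * Ho * Wo * b;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int k = (dj + 1) * 3 + (di + 1);
        for (int jo = 0; jo < Wo; ++jo) {
          int js = 2 * jo + dj;
          if (js < 0 || js >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            int is = 2 * io + di;
            if (is < 0 || is >= H) continue;
            std::memcpy(cb + Crow * ((size_t)io + (size_t)Ho * jo) + (size_t)k * Cin,
                        xb + (size_t)Cin * ((size_t)is + (size_t)H * js),
                        sizeof(float) * Cin);
          }
        }
      }
    }
  }
}

static void col2im(const fmat& dcols, int H, int W, int B, fmat& dx) {
  int Cin = dcols.n_rows / 9, Ho = out_sz(H), Wo = out_sz(W);
  dx.zeros(Cin, (size_t)H * W * B);
  const size_t Crow = 9 * (size_t)Cin;
  for (int b = 0; b < B; ++b) {
    float* xb = dx.memptr() + (size_t)Cin * H * W * b;
    const float* cb = dcols.memptr() + Crow * Ho * Wo * b;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int k = (dj + 1) * 3 + (di + 1);
        for (int jo = 0; jo < Wo; ++jo) {
          int js = 2 * jo + dj;
          if (js < 0 || js >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            int is = 2 * io + di;
            if (is < 0 || is >= H) continue;
            float* dst = xb + (size_t)Cin * ((size_t)is + (size_t)H * js);
            const float* src = cb + Crow * ((size_t)io + (size_t)Ho * jo) + (size_t)k * Cin;
            for (int c = 0; c < Cin; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
}

struct Weights {
  std::vector<fmat> W;   // conv: Cout x (9*Cin); dense: C x 128
  std::vector<fvec> b;   // conv biases are folded into the BN shift; dense bias used
  std::vector<fvec> g;   // batch-norm scale per conv layer
  std::vector<fvec> e;   // batch-norm shift per conv layer
  std::vector<fvec> rm;  // running mean (inference statistics)
  std::vector<fvec> rv;  // running variance
};

struct Cache {          // one sub-batch
  std::vector<fmat> cols;
  std::vector<fmat> xhat;      // BN-normalized pre-activation
  std::vector<fvec> invstd;
  std::vector<fmat> post;      // post-ReLU activations (ReLU mask)
  fmat gap;                    // 128 x B
};

static fvec as_fvec(NumericVector v) {
  fvec f(v.size());
  for (int i = 0; i < v.size(); ++i) f((uword)i) = (float)v[i];
  return f;
}

static NumericVector as_nv(const fvec& f) {
  NumericVector v(f.n_elem);
  for (uword i = 0; i < f.n_elem; ++i) v[i] = f(i);
  return v;
}

static Weights weights_from_list(List w) {
  Weights ww;
  for (int l = 0; l < NBLK; ++l) {
    NumericMatrix m = w["W" + std::to_string(l + 1)];
    fmat fm(m.nrow(), m.ncol());
    for (int j = 0; j < m.ncol(); ++j)
      for (int i = 0; i < m.nrow(); ++i) fm((uword)i, (uword)j) = (float)m(i, j);
    ww.W.push_back(fm);
    ww.b.push_back(as_fvec(w["b" + std::to_string(l + 1)]));
    ww.g.push_back(as_fvec(w["g" + std::to_string(l + 1)]));
    ww.e.push_back(as_fvec(w["e" + std::to_string(l + 1)]));
    ww.rm.push_back(as_fvec(w["rm" + std::to_string(l + 1)]));
    ww.rv.push_back(as_fvec(w["rv" + std::to_string(l + 1)]));
  }
  NumericMatrix md = w["Wd"];
  fmat fd(md.nrow(), md.ncol());
  for (int j = 0; j < md.ncol(); ++j)
    for (int i = 0; i < md.nrow(); ++i) fd((uword)i, (uword)j) = (float)md(i, j);
  ww.W.push_back(fd);
  ww.b.push_back(as_fvec(w["bd"]));
  return ww;
}

static List weights_to_list(const Weights& ww) {
  List out;
  for (int l = 0; l < NBLK; ++l) {
    NumericMatrix m(ww.W[l].n_rows, ww.W[l].n_cols);
    for (uword j = 0; j < ww.W[l].n_cols; ++j)
      for (uword i = 0; i < ww.W[l].n_rows; ++i) m(i, j) = ww.W[l](i, j);
    out["W" + std::to_string(l + 1)] = m;
    out["b" + std::to_string(l + 1)] = as_nv(ww.b[l]);
    out["g" + std::to_string(l + 1)] = as_nv(ww.g[l]);
    out["e" + std::to_string(l + 1)] = as_nv(ww.e[l]);
    out["rm" + std::to_string(l + 1)] = as_nv(ww.rm[l]);
    out["rv" + std::to_string(l + 1)] = as_nv(ww.rv[l]);
  }
  NumericMatrix md(ww.W[NBLK].n_rows, ww.W[NBLK].n_cols);
  for (uword j = 0; j < ww.W[NBLK].n_cols; ++j)
    for (uword i = 0; i < ww.W[NBLK].n_rows; ++i) md(i, j) = ww.W[NBLK](i, j);
  out["Wd"] = md;
  out["bd"] = as_nv(ww.b[NBLK]);
  return out;
}

static const float BN_EPS = 1e-5f;
static const float BN_MOM = 0.9f;   // running-statistics momentum

// forward a sub-batch; returns logits C x B. Cache filled if train = true;
// train also selects batch statistics (vs running statistics) for the BN.
static fmat forward(Weights& ww, const fmat& x0, int B, Cache& cc,
                    bool train, const std::vector<Dims>& dims) {
  if (train) {
    cc.cols.assign(NBLK, fmat());
    cc.xhat.assign(NBLK, fmat());
    cc.invstd.assign(NBLK, fvec());
    cc.post.assign(NBLK, fmat());
  }
  fmat act = x0, cols, y;
  for (int l = 0; l < NBLK; ++l) {
    im2col(act, dims[l].H, dims[l].W, B, cols);
    y = ww.W[l] * cols;
    // batch normalization per channel (rows of y)
    if (train) {
      fvec mu = arma::conv_to<fvec>::from(arma::mean(y, 1));
      y.each_col() -= mu;
      fvec var = arma::conv_to<fvec>::from(arma::mean(arma::square(y), 1));
      fvec inv = 1.0f / arma::sqrt(var + BN_EPS);
      y.each_col() %= inv;
      ww.rm[l] = BN_MOM * ww.rm[l] + (1.0f - BN_MOM) * mu;
      ww.rv[l] = BN_MOM * ww.rv[l] + (1.0f - BN_MOM) * var;
      cc.xhat[l] = y;
      cc.invstd[l] = inv;
    } else {
      y.each_col() -= ww.rm[l];
      y.each_col() %= 1.0f / arma::sqrt(ww.rv[l] + BN_EPS);
    }
    y.each_col() %= ww.g[l];
    y.each_col() += ww.e[l];
    y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    if (train) {
      cc.cols[l] = std::move(cols);
      cc.post[l] = y;
    }
    act = std::move(y);
  }
  // global average pool per image
  fmat gap(CH[NBLK], B);
  size_t npix = (size_t)dims[NBLK - 1].Ho * dims[NBLK - 1].Wo;
  for (int b = 0; b < B; ++b)
    gap.col((uword)b) = arma::conv_to<fvec>::from(
      arma::mean(act.cols((uword)(npix * b), (uword)(npix * (b + 1) - 1)), 1));
  if (train) cc.gap = gap;
  fmat logits = ww.W[NBLK] * gap;
  logits.each_col() += ww.b[NBLK];
  return logits;
}

// backward a sub-batch given dlogits (C x B); accumulates into grad.
static void backward(const Weights& ww, const Cache& cc, const fmat& dlogits,
                     int B, Weights& grad, const std::vector<Dims>& dims) {
  grad.W[NBLK] += dlogits * cc.gap.t();
  grad.b[NBLK] += arma::sum(dlogits, 1);
  fmat dgap = ww.W[NBLK].t() * dlogits;   // 128 x B

  int l = NBLK - 1;
  size_t npix = (size_t)dims[l].Ho * dims[l].Wo;
  fmat dy(CH[NBLK], npix * B);
  for (int b = 0; b < B; ++b) {
    fvec col = dgap.col((uword)b) / (float)npix;
    dy.cols((uword)(npix * b), (uword)(npix * (b + 1) - 1)).each_col() = col;
  }

  fmat dcols, dx;
  for (; l >= 0; --l) {
    dy.elem(arma::find(cc.post[l] <= 0.0f)).zeros();
    // batch-norm backward (per channel = per row)
    const fmat& xh = cc.xhat[l];
    float N = (float)dy.n_cols;
    fvec sum_dy = arma::conv_to<fvec>::from(arma::sum(dy, 1));
    fvec sum_dyxh = arma::conv_to<fvec>::from(arma::sum(dy % xh, 1));
    grad.e[l] += sum_dy;
    grad.g[l] += sum_dyxh;
    fmat dz = dy;
    dz.each_col() %= ww.g[l];
    fvec sdz = sum_dy % ww.g[l];
    fvec sdzxh = sum_dyxh % ww.g[l];
    dz -= xh.each_col() % (sdzxh / N);
    dz.each_col() -= sdz / N;
    dz.each_col() %= cc.invstd[l];
    grad.W[l] += dz * cc.cols[l].t();
    if (l > 0) {
      dcols = ww.W[l].t() * dz;
      col2im(dcols, dims[l].H, dims[l].W, B, dx);
      dy = std::move(dx);
    }
  }
}

// gather rows of X (images) into a float activation matrix 1 x (IMG*IMG*B)
static void gather(const NumericMatrix& X, const std::vector<int>& rows,
                   fmat& x0) {
  int B = rows.size(), npx = IMG * IMG;
  x0.set_size(1, (size_t)npx * B);
  for (int b = 0; b < B; ++b) {
    float* dst = x0.memptr() + (size_t)npx * b;
    int r = rows[b];
    for (int k = 0; k < npx; ++k) dst[k] = (float)X(r, k);
  }
}

// He-initialised weights; draws from the R RNG.
// [[Rcpp::export(name = ".cnn_init_cpp")]]
List cnn_init_cpp(int n_classes) {
  Weights ww;
  for (int l = 0; l < NBLK; ++l) {
    int fan_in = CH[l] * 9;
    double sd = std::sqrt(2.0 / fan_in);
    fmat W(CH[l + 1], fan_in);
    for (uword j = 0; j < W.n_cols; ++j)
      for (uword i = 0; i < W.n_rows; ++i) W(i, j) = (float)(sd * norm_rand());
    ww.W.push_back(W);
    ww.b.push_back(fvec(CH[l + 1], arma::fill::zeros));
    ww.g.push_back(fvec(CH[l + 1], arma::fill::ones));
    ww.e.push_back(fvec(CH[l + 1], arma::fill::zeros));
    ww.rm.push_back(fvec(CH[l + 1], arma::fill::zeros));
    ww.rv.push_back(fvec(CH[l + 1], arma::fill::ones));
  }
  double sd = std::sqrt(2.0 / CH[NBLK]);
  fmat Wd(n_classes, CH[NBLK]);
  for (uword j = 0; j < Wd.n_cols; ++j)
    for (uword i = 0; i < Wd.n_rows; ++i) Wd(i, j) = (float)(sd * norm_rand());
  ww.W.push_back(Wd);
  ww.b.push_back(fvec(n_classes, arma::fill::zeros));
  return weights_to_list(ww);
}

static void softmax_cols(fmat& z) {
  for (uword b = 0; b < z.n_cols; ++b) {
    fvec c = z.col(b);
    float m = c.max();
    c = arma::exp(c - m);
    z.col(b) = c / arma::accu(c);
  }
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
NumericMatrix cnn_predict_cpp(List weights, NumericMatrix X) {
  Weights ww = weights_from_list(weights);
  std::vector<Dims> dims = layer_dims();
  int n = X.nrow(), C = ww.b[NBLK].n_elem;
  if (X.ncol() != IMG * IMG) stop("images must be %d x %d", IMG, IMG);
  NumericMatrix out(n, C);
  Cache cc;
  fmat x0;
  for (int start = 0; start < n; start += SUB) {
    Rcpp::checkUserInterrupt();
    int B = std::min(SUB, n - start);
    std::vector<int> rows(B);
    for (int b = 0; b < B; ++b) rows[b] = start + b;
    gather(X, rows, x0);
    fmat z = forward(ww, x0, B, cc, false, dims);
    softmax_cols(z);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < C; ++c) out(start + b, c) = z((uword)c, (uword)b);
  }
  return out;
}

struct Adam {
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb, mg, vg, me, ve;
  long t = 0;
  void init(const Weights& ww) {
    for (size_t l = 0; l < ww.W.size(); ++l) {
      mW.push_back(fmat(ww.W[l].n_rows, ww.W[l].n_cols, arma::fill::zeros));
      vW.push_back(fmat(ww.W[l].n_rows, ww.W[l].n_cols, arma::fill::zeros));
      mb.push_back(fvec(ww.b[l].n_elem, arma::fill::zeros));
      vb.push_back(fvec(ww.b[l].n_elem, arma::fill::zeros));
    }
    for (size_t l = 0; l < ww.g.size(); ++l) {
      mg.push_back(fvec(ww.g[l].n_elem, arma::fill::zeros));
      vg.push_back(fvec(ww.g[l].n_elem, arma::fill::zeros));
      me.push_back(fvec(ww.e[l].n_elem, arma::fill::zeros));
      ve.push_back(fvec(ww.e[l].n_elem, arma::fill::zeros));
    }
  }
};

static void adam_step(Weights& ww, const Weights& grad, Adam& st, float lr) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  st.t += 1;
  float c1 = 1.0f - std::pow(b1, (float)st.t);
  float c2 = 1.0f - std::pow(b2, (float)st.t);
  for (size_t l = 0; l < ww.W.size(); ++l) {
    st.mW[l] = b1 * st.mW[l] + (1.0f - b1) * grad.W[l];
    st.vW[l] = b2 * st.vW[l] + (1.0f - b2) * arma::square(grad.W[l]);
    ww.W[l] -= lr * (st.mW[l] / c1) / (arma::sqrt(st.vW[l] / c2) + eps);
    st.mb[l] = b1 * st.mb[l] + (1.0f - b1) * grad.b[l];
    st.vb[l] = b2 * st.vb[l] + (1.0f - b2) * arma::square(grad.b[l]);
    ww.b[l] -= lr * (st.mb[l] / c1) / (arma::sqrt(st.vb[l] / c2) + eps);
  }
  for (size_t l = 0; l < ww.g.size(); ++l) {      // BN affine parameters
    st.mg[l] = b1 * st.mg[l] + (1.0f - b1) * grad.g[l];
    st.vg[l] = b2 * st.vg[l] + (1.0f - b2) * arma::square(grad.g[l]);
    ww.g[l] -= lr * (st.mg[l] / c1) / (arma::sqrt(st.vg[l] / c2) + eps);
    st.me[l] = b1 * st.me[l] + (1.0f - b1) * grad.e[l];
    st.ve[l] = b2 * st.ve[l] + (1.0f - b2) * arma::square(grad.e[l]);
    ww.e[l] -= lr * (st.me[l] / c1) / (arma::sqrt(st.ve[l] / c2) + eps);
  }
}

static void eval_set(Weights& ww, const NumericMatrix& X,
                     const IntegerVector& y, const std::vector<Dims>& dims,
                     double& loss, double& acc) {
  int n = X.nrow(), C = ww.b[NBLK].n_elem;
  double L = 0.0; int ok = 0;
  Cache cc;
  fmat x0;
  for (int start = 0; start < n; start += SUB) {
    Rcpp::checkUserInterrupt();
    int B = std::min(SUB, n - start);
    std::vector<int> rows(B);
    for (int b = 0; b < B; ++b) rows[b] = start + b;
    gather(X, rows, x0);
    fmat z = forward(ww, x0, B, cc, false, dims);
    for (int b = 0; b < B; ++b) {
      fvec c = z.col((uword)b);
      float m = c.max();
      L += m + std::log(arma::accu(arma::exp(c - m))) - c((uword)y[start + b]);
      int pred = 0;
      for (int cl = 1; cl < C; ++cl) if (c((uword)cl) > c((uword)pred)) pred = cl;
      if (pred == y[start + b]) ++ok;
    }
  }
  loss = L / n;
  acc = (double)ok / n;
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(List weights, NumericMatrix X, IntegerVector y,
                   NumericMatrix Xtest, IntegerVector ytest,
                   int epochs, int batch, double lr,
                   bool literal_rule, bool verbose) {
  Weights ww = weights_from_list(weights);
  std::vector<Dims> dims = layer_dims();
  int n = X.nrow(), C = ww.b[NBLK].n_elem;
  if (X.ncol() != IMG * IMG) stop("images must be %d x %d", IMG, IMG);

  Adam st; st.init(ww);
  Weights grad = ww;
  Weights best = ww;
  double best_acc = -1.0;
  int best_epoch = 0;
  double prev_test_acc = NA_REAL;
  int literal_epoch = 0;

  NumericVector h_trl(epochs), h_tra(epochs), h_tel(epochs), h_tea(epochs);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  Cache cc;
  fmat x0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n - 1; i > 0; --i) {   // Fisher-Yates with the R RNG
      int j = (int)((i + 1) * unif_rand()); if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double L = 0.0; int ok = 0;
    for (int start = 0; start < n; start += batch) {
      int bend = std::min(n, start + batch);
      int bs = bend - start;
      for (size_t l = 0; l < grad.W.size(); ++l) {
        grad.W[l].zeros(); grad.b[l].zeros();
        if (l < grad.g.size()) { grad.g[l].zeros(); grad.e[l].zeros(); }
      }
      for (int s0 = start; s0 < bend; s0 += SUB) {
        Rcpp::checkUserInterrupt();
        int B = std::min(SUB, bend - s0);
        std::vector<int> rows(perm.begin() + s0, perm.begin() + s0 + B);
        gather(X, rows, x0);
        fmat z = forward(ww, x0, B, cc, true, dims);
        fmat pr = z;
        softmax_cols(pr);
        fmat dz = pr;
        for (int b = 0; b < B; ++b) {
          int lab = y[rows[b]];
          fvec c = z.col((uword)b);
          float m = c.max();
          L += m + std::log(arma::accu(arma::exp(c - m))) - c((uword)lab);
          if ((int)pr.col((uword)b).index_max() == lab) ++ok;
          dz((uword)lab, (uword)b) -= 1.0f;
        }
        dz /= (float)bs;
        backward(ww, cc, dz, B, grad, dims);
      }
      adam_step(ww, grad, st, (float)lr);
    }
    double tel, tea;
    eval_set(ww, Xtest, ytest, dims, tel, tea);
    h_trl[ep] = L / n; h_tra[ep] = (double)ok / n;
    h_tel[ep] = tel; h_tea[ep] = tea;
    if (literal_rule) {
      // accept the weights of the last epoch in which the test accuracy
      // decreased with respect to its previous value
      if (!ISNA(prev_test_acc) && tea < prev_test_acc) {
        best = ww; literal_epoch = ep + 1; best_epoch = ep + 1;
      }
    } else if (tea > best_acc) {
      best_acc = tea; best = ww; best_epoch = ep + 1;
    }
    if (!ISNA(prev_test_acc) && tea < prev_test_acc) literal_epoch = ep + 1;
    prev_test_acc = tea;
    if (verbose)
      Rcout << "epoch " << ep + 1 << ": train loss " << h_trl[ep]
            << ", train acc " << h_tra[ep] << ", test acc " << tea << "\n";
  }
  if (best_epoch == 0) best = ww;   // literal rule with no decrease observed
  List hist = List::create(_["epoch"] = seq_len(epochs),
                           _["train_loss"] = h_trl, _["train_acc"] = h_tra,
                           _["test_loss"] = h_tel, _["test_acc"] = h_tea);
  return List::create(_["weights"] = weights_to_list(best),
                      _["final_weights"] = weights_to_list(ww),
                      _["history"] = hist,
                      _["best_epoch"] = best_epoch,
                      _["literal_epoch"] = literal_epoch,
                      _["n_classes"] = C);
}
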