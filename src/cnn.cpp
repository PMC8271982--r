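// Small convolutional network for 15x32x3 action images.
//
// Architecture: six 3x3 conv layers (64,64,128,128,256,256), each followed
// by batch normalization and ReLU; 2x2 max-pooling after conv 2 and conv 4;
// global average pooling after conv 6; one fully connected softmax head.
// Width chain 32 -> 16 -> 8; height 15 -> 7 -> 3 (floor pooling).
//
// Everything runs in single precision. Activations are stored as
// [B*H*W x C] matrices (within a sample, rows are column-major over the
// H x W grid, h fastest), so convolution is im2col + one SGEMM per layer
// and batch normalization is a per-column reduction.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace arma;

static const int NLAYER = 6;
static const int CH[NLAYER + 1] = {3, 64, 64, 128, 128, 256, 256};
static const int LH[NLAYER] = {15, 15, 7, 7, 3, 3};
static const int LW[NLAYER] = {32, 32, 16, 16, 8, 8};
static const float BN_EPS = 1e-5f;
static const float BN_MOM = 0.1f;

struct ConvParams {
  fmat W;            // [Cin*9 x Cout]
  fvec b, g, be;     // bias, BN gamma, BN beta  [Cout]
  fvec rm, rv;       // BN running mean / variance [Cout]
};

struct Net {
  ConvParams conv[NLAYER];
  fmat Wfc;          // [256 x K]
  fvec bfc;          // [K]
  int n_classes() const { return (int)Wfc.n_cols; }
};

// ---- parameter list <-> Net ------------------------------------------------

static fmat as_fmat(SEXP s) {
  Rcpp::NumericMatrix m(s);
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}

static fvec as_fvec(SEXP s) {
  Rcpp::NumericVector v(s);
  fvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

static Rcpp::NumericMatrix wrap_fmat(const fmat& m) {
  Rcpp::NumericMatrix out(m.n_rows, m.n_cols);
  for (size_t j = 0; j < m.n_cols; ++j)
    for (size_t i = 0; i < m.n_rows; ++i) out(i, j) = m(i, j);
  return out;
}

static Rcpp::NumericVector wrap_fvec(const fvec& v) {
  Rcpp::NumericVector out(v.n_elem);
  for (size_t i = 0; i < v.n_elem; ++i) out[i] = v[i];
  return out;
}

static Net net_from_list(const Rcpp::List& p) {
  Net net;
  for (int l = 0; l < NLAYER; ++l) {
    std::string s = std::to_string(l + 1);
    net.conv[l].W  = as_fmat(p["W" + s]);
    net.conv[l].b  = as_fvec(p["b" + s]);
    net.conv[l].g  = as_fvec(p["g" + s]);
    net.conv[l].be = as_fvec(p["be" + s]);
    net.conv[l].rm = as_fvec(p["rm" + s]);
    net.conv[l].rv = as_fvec(p["rv" + s]);
    if ((int)net.conv[l].W.n_rows != CH[l] * 9 ||
        (int)net.conv[l].W.n_cols != CH[l + 1])
      Rcpp::stop("conv layer %d has wrong weight shape", l + 1);
  }
  net.Wfc = as_fmat(p["Wfc"]);
  net.bfc = as_fvec(p["bfc"]);
  if ((int)net.Wfc.n_rows != CH[NLAYER])
    Rcpp::stop("fully connected layer has wrong input width");
  return net;
}

static Rcpp::List net_to_list(const Net& net) {
  Rcpp::List p;
  for (int l = 0; l < NLAYER; ++l) {
    std::string s = std::to_string(l + 1);
    p["W" + s]  = wrap_fmat(net.conv[l].W);
    p["b" + s]  = wrap_fvec(net.conv[l].b);
    p["g" + s]  = wrap_fvec(net.conv[l].g);
    p["be" + s] = wrap_fvec(net.conv[l].be);
    p["rm" + s] = wrap_fvec(net.conv[l].rm);
    p["rv" + s] = wrap_fvec(net.conv[l].rv);
  }
  p["Wfc"] = wrap_fmat(net.Wfc);
  p["bfc"] = wrap_fvec(net.bfc);
  return p;
}

// ---- layer primitives ------------------------------------------------------

// X: [B*HW x C]; col: [B*HW x C*9], zero padded 3x3 neighborhoods.
// A 3x3 offset (kh, kw) is a uniform shift of sh = (kh-1) + (kw-1)*H within
// each sample block, so each column is one block memcpy plus border zeroing.
static void im2col(const fmat& X, int C, int H, int W, int B, fmat& col) {
  const int HW = H * W;
  col.set_size(X.n_rows, (size_t)C * 9);
  for (int c = 0; c < C; ++c) {
    const float* src = X.colptr(c);
    for (int kh = 0; kh < 3; ++kh) {
      for (int kw = 0; kw < 3; ++kw) {
        float* dst = col.colptr((size_t)c * 9 + kh * 3 + kw);
        const int sh = (kh - 1) + (kw - 1) * H;
        const int t0 = std::max(0, -sh);
        const int t1 = HW - std::max(0, sh);
        for (int s = 0; s < B; ++s) {
          float* d = dst + (size_t)s * HW;
          const float* x = src + (size_t)s * HW;
          if (t0 > 0) std::memset(d, 0, sizeof(float) * t0);
          if (t1 < HW) std::memset(d + t1, 0, sizeof(float) * (HW - t1));
          std::memcpy(d + t0, x + t0 + sh, sizeof(float) * (t1 - t0));
          if (kh == 0)
            for (int w = 0; w < W; ++w) d[(size_t)w * H] = 0.0f;
          else if (kh == 2)
            for (int w = 0; w < W; ++w) d[(size_t)w * H + H - 1] = 0.0f;
          if (kw == 0) std::memset(d, 0, sizeof(float) * H);
          else if (kw == 2)
            std::memset(d + (size_t)(W - 1) * H, 0, sizeof(float) * H);
        }
      }
    }
  }
}

// Scatter-add of dcol back onto dX (transpose of im2col). Gradient entries
// at padding positions are zeroed first, after which each column is one
// shifted vector add per sample block. Mutates dcol.
static void col2im(fmat& dcol, int C, int H, int W, int B, fmat& dX) {
  const int HW = H * W;
  dX.zeros(dcol.n_rows, C);
  for (int c = 0; c < C; ++c) {
    float* dst = dX.colptr(c);
    for (int kh = 0; kh < 3; ++kh) {
      for (int kw = 0; kw < 3; ++kw) {
        float* src = dcol.colptr((size_t)c * 9 + kh * 3 + kw);
        const int sh = (kh - 1) + (kw - 1) * H;
        const int t0 = std::max(0, -sh);
        const int t1 = HW - std::max(0, sh);
        for (int s = 0; s < B; ++s) {
          float* sp = src + (size_t)s * HW;
          if (kh == 0)
            for (int w = 0; w < W; ++w) sp[(size_t)w * H] = 0.0f;
          else if (kh == 2)
            for (int w = 0; w < W; ++w) sp[(size_t)w * H + H - 1] = 0.0f;
          if (kw == 0) std::memset(sp, 0, sizeof(float) * H);
          else if (kw == 2)
            std::memset(sp + (size_t)(W - 1) * H, 0, sizeof(float) * H);
          float* d = dst + (size_t)s * HW + t0 + sh;
          const float* x = sp + t0;
          const int len = t1 - t0;
          for (int i = 0; i < len; ++i) d[i] += x[i];
        }
      }
    }
  }
}

// 2x2 max pooling with floor semantics; records argmax rows for backward.
static void maxpool(const fmat& X, int H, int W, int B,
                    fmat& Y, umat& argmax) {
  const int C = X.n_cols, H2 = H / 2, W2 = W / 2;
  const int HW = H * W, HW2 = H2 * W2;
  Y.set_size((size_t)B * HW2, C);
  argmax.set_size((size_t)B * HW2, C);
  for (int c = 0; c < C; ++c) {
    const float* src = X.colptr(c);
    float* dst = Y.colptr(c);
    uword* am = argmax.colptr(c);
    for (int s = 0; s < B; ++s) {
      const size_t off = (size_t)s * HW, off2 = (size_t)s * HW2;
      for (int w2 = 0; w2 < W2; ++w2) {
        for (int h2 = 0; h2 < H2; ++h2) {
          size_t best = off + (size_t)(2 * w2) * H + 2 * h2;
          float bv = src[best];
          const size_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int k = 0; k < 3; ++k)
            if (src[cand[k]] > bv) { bv = src[cand[k]]; best = cand[k]; }
          dst[off2 + (size_t)w2 * H2 + h2] = bv;
          am[off2 + (size_t)w2 * H2 + h2] = best;
        }
      }
    }
  }
}

static void maxpool_back(const fmat& dY, const umat& argmax,
                         size_t rows_in, fmat& dX) {
  dX.zeros(rows_in, dY.n_cols);
  for (size_t c = 0; c < dY.n_cols; ++c) {
    const float* g = dY.colptr(c);
    const uword* am = argmax.colptr(c);
    float* dst = dX.colptr(c);
    for (size_t i = 0; i < dY.n_rows; ++i) dst[am[i]] += g[i];
  }
}

struct BNCache { frowvec mean, ivar; fmat xhat; };

static void bn_forward_train(fmat& X, ConvParams& p, BNCache& cache) {
  const float m = (float)X.n_rows;
  frowvec mu = sum(X, 0) / m;
  X.each_row() -= mu;
  frowvec var = sum(square(X), 0) / m;
  frowvec ivar = 1.0f / sqrt(var + BN_EPS);
  X.each_row() %= ivar;
  cache.mean = mu; cache.ivar = ivar; cache.xhat = X;
  X.each_row() %= p.g.t();
  X.each_row() += p.be.t();
  p.rm = (1.0f - BN_MOM) * p.rm + BN_MOM * mu.t();
  p.rv = (1.0f - BN_MOM) * p.rv + BN_MOM * var.t();
}

static void bn_forward_eval(fmat& X, const ConvParams& p) {
  frowvec ivar = 1.0f / sqrt(p.rv.t() + BN_EPS);
  X.each_row() -= p.rm.t();
  X.each_row() %= (ivar % p.g.t());
  X.each_row() += p.be.t();
}

// dY in place -> dX; accumulates dg, dbe.
static void bn_backward(fmat& dY, const BNCache& cache, const ConvParams& p,
                        fvec& dg, fvec& dbe) {
  const float m = (float)dY.n_rows;
  dg  = sum(dY % cache.xhat, 0).t();
  dbe = sum(dY, 0).t();
  // dX = (g*ivar/m) * (m*dY - sum(dY) - xhat * sum(dY*xhat))
  frowvec sdY = sum(dY, 0);
  frowvec sdYx = sum(dY % cache.xhat, 0);
  dY *= m;
  dY.each_row() -= sdY;
  dY -= cache.xhat.each_row() % sdYx;
  dY.each_row() %= (p.g.t() % cache.ivar) / m;
}

static fmat softmax_rows(fmat logits) {
  fvec mx = max(logits, 1);
  logits.each_col() -= mx;
  logits = exp(logits);
  fvec s = sum(logits, 1);
  logits.each_col() /= s;
  return logits;
}

// ---- forward pass ----------------------------------------------------------

struct FwdCache {
  fmat col[NLAYER];     // im2col inputs
  BNCache bn[NLAYER];
  fmat relu[NLAYER];    // post-ReLU activations
  umat pool_arg[2];
  size_t pool_rows_in[2];
  fmat gap;             // [B x 256]
  fmat probs;           // [B x K]
};

// X0: [B*480 x 3] input activations (already scaled to [0,1]).
static fmat forward(Net& net, const fmat& X0, int B, bool training,
                    FwdCache* cache) {
  fmat act = X0;
  int npool = 0;
  for (int l = 0; l < NLAYER; ++l) {
    fmat col;
    im2col(act, CH[l], LH[l], LW[l], B, col);
    act = col * net.conv[l].W;
    act.each_row() += net.conv[l].b.t();
    if (training) {
      cache->col[l] = std::move(col);
      bn_forward_train(act, net.conv[l], cache->bn[l]);
    } else {
      bn_forward_eval(act, net.conv[l]);
    }
    act.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    if (training) cache->relu[l] = act;
    if (l == 1 || l == 3) {
      fmat pooled; umat am;
      size_t rows_in = act.n_rows;
      maxpool(act, LH[l], LW[l], B, pooled, am);
      if (training) {
        cache->pool_arg[npool] = std::move(am);
        cache->pool_rows_in[npool] = rows_in;
      }
      ++npool;
      act = std::move(pooled);
    }
  }
  // global average pooling over the 3x8 grid
  const int HW = LH[NLAYER - 1] * LW[NLAYER - 1];
  fmat gap(B, CH[NLAYER]);
  for (int c = 0; c < CH[NLAYER]; ++c) {
    const float* src = act.colptr(c);
    for (int s = 0; s < B; ++s) {
      float acc = 0.0f;
      for (int i = 0; i < HW; ++i) acc += src[(size_t)s * HW + i];
      gap(s, c) = acc / HW;
    }
  }
  fmat logits = gap * net.Wfc;
  logits.each_row() += net.bfc.t();
  fmat probs = softmax_rows(logits);
  if (cache) { cache->gap = std::move(gap); cache->probs = probs; }
  if (!training && cache) cache->relu[NLAYER - 1] = std::move(act);
  return probs;
}

// ---- gradients -------------------------------------------------------------

struct Grads {
  fmat dW[NLAYER]; fvec db[NLAYER], dg[NLAYER], dbe[NLAYER];
  fmat dWfc; fvec dbfc;
};

static float backward(Net& net, FwdCache& cache, const uvec& y, int B,
                      Grads& gr) {
  const int K = net.n_classes();
  // cross-entropy loss and dlogits
  float loss = 0.0f;
  fmat dlogits = cache.probs;
  for (int s = 0; s < B; ++s) {
    loss -= std::log(std::max(cache.probs(s, (uword)y[s]), 1e-12f));
    dlogits(s, (uword)y[s]) -= 1.0f;
  }
  loss /= B;
  dlogits /= (float)B;

  gr.dWfc = cache.gap.t() * dlogits;
  gr.dbfc = sum(dlogits, 0).t();
  fmat dgap = dlogits * net.Wfc.t();   // [B x 256]

  const int HW = LH[NLAYER - 1] * LW[NLAYER - 1];
  fmat dact((size_t)B * HW, CH[NLAYER]);
  for (int c = 0; c < CH[NLAYER]; ++c) {
    float* dst = dact.colptr(c);
    for (int s = 0; s < B; ++s) {
      const float v = dgap(s, c) / HW;
      for (int i = 0; i < HW; ++i) dst[(size_t)s * HW + i] = v;
    }
  }

  int npool = 2;
  for (int l = NLAYER - 1; l >= 0; --l) {
    if (l == 1 || l == 3) {
      --npool;
      fmat up;
      maxpool_back(dact, cache.pool_arg[npool], cache.pool_rows_in[npool], up);
      dact = std::move(up);
    }
    // ReLU
    {
      const float* r = cache.relu[l].memptr();
      float* g = dact.memptr();
      const size_t n = dact.n_elem;
      for (size_t i = 0; i < n; ++i)
        if (r[i] <= 0.0f) g[i] = 0.0f;
    }
    // BN
    bn_backward(dact, cache.bn[l], net.conv[l], gr.dg[l], gr.dbe[l]);
    // conv
    gr.dW[l] = cache.col[l].t() * dact;
    gr.db[l] = sum(dact, 0).t();
    if (l > 0) {
      fmat dcol = dact * net.conv[l].W.t();
      col2im(dcol, CH[l], LH[l], LW[l], B, dact);
    }
  }
  return loss;
}

// ---- exported functions ----------------------------------------------------

// He-uniform initialization; zero_fc gives a zero-weight softmax head.
// [[Rcpp::export(name = ".cnn_init")]]
Rcpp::List cnn_init(int n_classes, int seed, bool zero_fc = false) {
  if (n_classes < 2) Rcpp::stop("n_classes must be >= 2");
  std::mt19937 rng((uint32_t)seed);
  Net net;
  for (int l = 0; l < NLAYER; ++l) {
    const int fan_in = CH[l] * 9;
    const float lim = std::sqrt(6.0f / fan_in);
    std::uniform_real_distribution<float> U(-lim, lim);
    net.conv[l].W.set_size(fan_in, CH[l + 1]);
    for (size_t j = 0; j < net.conv[l].W.n_cols; ++j)
      for (size_t i = 0; i < net.conv[l].W.n_rows; ++i)
        net.conv[l].W(i, j) = U(rng);
    net.conv[l].b.zeros(CH[l + 1]);
    net.conv[l].g.ones(CH[l + 1]);
    net.conv[l].be.zeros(CH[l + 1]);
    net.conv[l].rm.zeros(CH[l + 1]);
    net.conv[l].rv.ones(CH[l + 1]);
  }
  net.Wfc.set_size(CH[NLAYER], n_classes);
  if (zero_fc) {
    net.Wfc.zeros();
  } else {
    const float lim = std::sqrt(6.0f / CH[NLAYER]);
    std::uniform_real_distribution<float> U(-lim, lim);
    for (size_t j = 0; j < net.Wfc.n_cols; ++j)
      for (size_t i = 0; i < net.Wfc.n_rows; ++i) net.Wfc(i, j) = U(rng);
  }
  net.bfc.zeros(n_classes);
  return net_to_list(net);
}

// Mini-batch SGD with momentum, L2 weight decay on conv/FC weights, and a
// step learning-rate schedule (lr = lr0 * factor^floor((epoch-1)/step)).
// X: [1440 x N] scaled inputs, y: 0-based labels.
// [[Rcpp::export(name = ".cnn_train")]]
Rcpp::List cnn_train(Rcpp::List params, Rcpp::NumericMatrix X,
                     Rcpp::IntegerVector y, int epochs, int batch_size,
                     double lr0, int lr_step, double lr_factor,
                     double momentum, double weight_decay, int seed) {
  const int N = X.ncol();
  if (N < 1) Rcpp::stop("no training samples");
  if ((int)X.nrow() != 15 * 32 * 3) Rcpp::stop("inputs must be 15x32x3 images");
  Net net = net_from_list(params);
  const int K = net.n_classes();
  for (int i = 0; i < N; ++i)
    if (y[i] < 0 || y[i] >= K) Rcpp::stop("label out of range");

  // reorder input features [15,32,3] (h,w,c column-major) -> rows h+w*15 per
  // channel column of a [480*B x 3] activation matrix, built per batch below
  std::mt19937 rng((uint32_t)seed);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;

  Net vel;  // momentum buffers, zero-initialized with matching shapes
  for (int l = 0; l < NLAYER; ++l) {
    vel.conv[l].W.zeros(size(net.conv[l].W));
    vel.conv[l].b.zeros(size(net.conv[l].b));
    vel.conv[l].g.zeros(size(net.conv[l].g));
    vel.conv[l].be.zeros(size(net.conv[l].be));
  }
  vel.Wfc.zeros(size(net.Wfc));
  vel.bfc.zeros(size(net.bfc));

  const int HW0 = 15 * 32;
  Rcpp::NumericVector hist_loss(epochs), hist_acc(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    const float lr = (float)(lr0 * std::pow(lr_factor, ep / lr_step));
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0; int ep_correct = 0, nb = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int B = std::min(batch_size, N - start);
      fmat X0((size_t)B * HW0, 3);
      uvec yb(B);
      for (int s = 0; s < B; ++s) {
        const int j = idx[start + s];
        yb[s] = (uword)y[j];
        for (int c = 0; c < 3; ++c)
          for (int i = 0; i < HW0; ++i)
            X0((size_t)s * HW0 + i, c) = (float)X(c * HW0 + i, j);
      }
      FwdCache cache;
      fmat probs = forward(net, X0, B, true, &cache);
      for (int s = 0; s < B; ++s)
        if ((uword)probs.row(s).index_max() == yb[s]) ++ep_correct;
      Grads gr;
      float loss = backward(net, cache, yb, B, gr);
      ep_loss += loss; ++nb;

      const float wd = (float)weight_decay, mom = (float)momentum;
      for (int l = 0; l < NLAYER; ++l) {
        gr.dW[l] += wd * net.conv[l].W;
        vel.conv[l].W  = mom * vel.conv[l].W  + gr.dW[l];
        vel.conv[l].b  = mom * vel.conv[l].b  + gr.db[l];
        vel.conv[l].g  = mom * vel.conv[l].g  + gr.dg[l];
        vel.conv[l].be = mom * vel.conv[l].be + gr.dbe[l];
        net.conv[l].W  -= lr * vel.conv[l].W;
        net.conv[l].b  -= lr * vel.conv[l].b;
        net.conv[l].g  -= lr * vel.conv[l].g;
        net.conv[l].be -= lr * vel.conv[l].be;
      }
      gr.dWfc += wd * net.Wfc;
      vel.Wfc = mom * vel.Wfc + gr.dWfc;
      vel.bfc = mom * vel.bfc + gr.dbfc;
      net.Wfc -= lr * vel.Wfc;
      net.bfc -= lr * vel.bfc;
      Rcpp::checkUserInterrupt();
    }
    hist_loss[ep] = ep_loss / nb;
    hist_acc[ep] = 100.0 * ep_correct / N;
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = net_to_list(net),
      Rcpp::Named("loss") = hist_loss,
      Rcpp::Named("accuracy") = hist_acc);
}

// Evaluation-mode forward pass. Returns class probabilities and, on request,
// the post-ReLU feature maps of the last convolution (3x8x256 per sample).
// [[Rcpp::export(name = ".cnn_forward")]]
Rcpp::List cnn_forward(Rcpp::List params, Rcpp::NumericMatrix X,
                       bool want_fmaps = false) {
  const int N = X.ncol();
  if ((int)X.nrow() != 15 * 32 * 3) Rcpp::stop("inputs must be 15x32x3 images");
  Net net = net_from_list(params);
  const int HW0 = 15 * 32;
  fmat X0((size_t)N * HW0, 3);
  for (int j = 0; j < N; ++j)
    for (int c = 0; c < 3; ++c)
      for (int i = 0; i < HW0; ++i)
        X0((size_t)j * HW0 + i, c) = (float)X(c * HW0 + i, j);
  FwdCache cache;
  fmat probs = forward(net, X0, N, false, &cache);
  Rcpp::List out;
  Rcpp::NumericMatrix pr(N, net.n_classes());
  for (int j = 0; j < net.n_classes(); ++j)
    for (int i = 0; i < N; ++i) pr(i, j) = probs(i, j);
  out["probs"] = pr;
  if (want_fmaps) {
    // cache.relu[5]: [N*24 x 256]; emit as [24*256 x N] (h,w column-major,
    // then channel) for easy reshaping to array(3, 8, 256) in R
    const fmat& fm = cache.relu[NLAYER - 1];
    const int HW = 24, C = CH[NLAYER];
    Rcpp::NumericMatrix fmo(HW * C, N);
    for (int s = 0; s < N; ++s)
      for (int c = 0; c < C; ++c)
        for (int i = 0; i < HW; ++i)
          fmo(c * HW + i, s) = fm((size_t)s * HW + i, c);
    out["fmaps"] = fmo;
  }
  return out;
}
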