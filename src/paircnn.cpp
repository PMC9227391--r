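// Two-branch ("pseudo-Siamese") 1D convolutional network for spectral
// pairs.  Each branch is a stack of conv(ReLU, "same" padding, stride 1)
// + non-overlapping max-pool blocks; branch outputs are concatenated,
// flattened, passed through dense(ReLU) -> dropout -> dense(sigmoid).
// Loss is binary cross-entropy, optimiser is Adam.  Single precision;
// convolutions run as im2col + BLAS sgemm, with whole minibatches
// concatenated along the length axis so every layer is one GEMM.
//
// Weight layout (flat list, fixed order; names are informational only):
//   branch{1,2}_conv{l}_W : n_kernels x (C_in * kernel_size), column
//                           index = tap * C_in + channel (tap-major)
//   branch{1,2}_conv{l}_b : n_kernels x 1
//   dense_W (units x F), dense_b (units x 1),
//   out_W (1 x units), out_b (1 x 1)
// where F = 2 * n_kernels * (input_length / pool^depth).

#include <RcppArmadillo.h>
#include <random>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::umat;

struct NetConfig {
  int depth, nk, ks, pool, dense;
  float dropout, lr;
  int epochs, batch;
};

static NetConfig parseConfig(const List& cfg) {
  NetConfig c;
  c.depth   = as<int>(cfg["nConvLayers"]);
  c.nk      = as<int>(cfg["nKernels"]);
  c.ks      = as<int>(cfg["kernelSize"]);
  c.pool    = as<int>(cfg["poolSize"]);
  c.dense   = as<int>(cfg["denseUnits"]);
  c.dropout = (float) as<double>(cfg["dropoutRate"]);
  c.lr      = (float) as<double>(cfg["learningRate"]);
  c.epochs  = as<int>(cfg["epochs"]);
  c.batch   = as<int>(cfg["batchSize"]);
  return c;
}

// ---- primitives ----------------------------------------------------------

// im2col for one sample: x cols [x0, x0+L) of X, writes out cols
// [o0, o0+Lo).  Row t*C + c of the output holds x(c, p + t - pad).
static void im2colInto(const fmat& X, int x0, int L, int ks, bool same,
                       fmat& out, int o0) {
  const int C = X.n_rows;
  const int pad = same ? (ks - 1) / 2 : 0;
  const int Lo = same ? L : L - ks + 1;
  for (int t = 0; t < ks; ++t) {
    const int shift = t - pad;
    const int lo = std::max(0, -shift);
    const int hi = std::min(Lo, L - shift);
    if (hi > lo)
      out.submat(t * C, o0 + lo, t * C + C - 1, o0 + hi - 1) =
          X.cols(x0 + lo + shift, x0 + hi - 1 + shift);
    // zero the padded fringes (buffers are reused across batches)
    if (lo > 0)
      out.submat(t * C, o0, t * C + C - 1, o0 + lo - 1).zeros();
    if (hi < Lo)
      out.submat(t * C, o0 + hi, t * C + C - 1, o0 + Lo - 1).zeros();
  }
}

static void col2imInto(const fmat& dcol, int c0, int Lo, int C, int L,
                       int ks, bool same, fmat& dx, int x0) {
  const int pad = same ? (ks - 1) / 2 : 0;
  dx.cols(x0, x0 + L - 1).zeros();
  for (int t = 0; t < ks; ++t) {
    const int shift = t - pad;
    const int lo = std::max(0, -shift);
    const int hi = std::min(Lo, L - shift);
    if (hi > lo)
      dx.cols(x0 + lo + shift, x0 + hi - 1 + shift) +=
          dcol.submat(t * C, c0 + lo, t * C + C - 1, c0 + hi - 1);
  }
}

// non-overlapping windowed max over a batch matrix; window never
// crosses a sample boundary because sample lengths divide by the pool
static void maxpoolBatch(const fmat& a, int size, int stride,
                         fmat& p, umat& idx) {
  const int C = a.n_rows;
  const int Lo = p.n_cols;
  for (int j = 0; j < Lo; ++j) {
    const int s = j * stride;
    for (int c = 0; c < C; ++c) {
      float best = a(c, s);
      int bi = s;
      for (int t = 1; t < size; ++t)
        if (a(c, s + t) > best) { best = a(c, s + t); bi = s + t; }
      p(c, j) = best;
      idx(c, j) = bi;
    }
  }
}

static inline void reluInPlace(fmat& z) {
  float* ptr = z.memptr();
  const arma::uword n = z.n_elem;
  for (arma::uword i = 0; i < n; ++i) ptr[i] = ptr[i] > 0.0f ? ptr[i] : 0.0f;
}

static inline float sigmoidf(float x) {
  return 1.0f / (1.0f + std::exp(-x));
}

// ---- weight plumbing -----------------------------------------------------

static std::vector<fmat> weightsFromR(const List& w) {
  std::vector<fmat> par;
  par.reserve(w.size());
  for (int i = 0; i < w.size(); ++i)
    par.push_back(arma::conv_to<fmat>::from(as<arma::mat>(w[i])));
  return par;
}

static List weightsToR(const std::vector<fmat>& par, const NetConfig& c) {
  List w(par.size());
  CharacterVector nm(par.size());
  int i = 0;
  for (int b = 1; b <= 2; ++b)
    for (int l = 1; l <= c.depth; ++l) {
      nm[i] = "branch" + std::to_string(b) + "_conv" + std::to_string(l) + "_W";
      ++i;
      nm[i] = "branch" + std::to_string(b) + "_conv" + std::to_string(l) + "_b";
      ++i;
    }
  nm[i++] = "dense_W"; nm[i++] = "dense_b";
  nm[i++] = "out_W";   nm[i++] = "out_b";
  for (size_t j = 0; j < par.size(); ++j)
    w[j] = wrap(arma::conv_to<arma::mat>::from(par[j]));
  w.attr("names") = nm;
  return w;
}

// Glorot-uniform initialisation, one mt19937 stream for everything
// [[Rcpp::export]]
List cpp_init_weights(List cfgL, int input_length, int seed) {
  NetConfig c = parseConfig(cfgL);
  std::mt19937 gen((unsigned) seed);
  std::vector<fmat> par;
  auto glorot = [&](int rows, int cols, int fan_in, int fan_out) {
    float lim = std::sqrt(6.0f / (float)(fan_in + fan_out));
    std::uniform_real_distribution<float> U(-lim, lim);
    fmat W(rows, cols);
    for (arma::uword j = 0; j < W.n_elem; ++j) W(j) = U(gen);
    return W;
  };
  for (int b = 0; b < 2; ++b)
    for (int l = 0; l < c.depth; ++l) {
      int cin = (l == 0) ? 1 : c.nk;
      par.push_back(glorot(c.nk, cin * c.ks, cin * c.ks, c.nk * c.ks));
      par.push_back(fmat(c.nk, 1, arma::fill::zeros));
    }
  int Lf = input_length;
  for (int l = 0; l < c.depth; ++l) Lf /= c.pool;
  int F = 2 * c.nk * Lf;
  par.push_back(glorot(c.dense, F, F, c.dense));
  par.push_back(fmat(c.dense, 1, arma::fill::zeros));
  par.push_back(glorot(1, c.dense, c.dense, 1));
  par.push_back(fmat(1, 1, arma::fill::zeros));
  return weightsToR(par, c);
}

// ---- batched workspace ---------------------------------------------------

// per-layer buffers sized for a maximal batch; the live batch uses the
// leading columns
struct LayerBuf {
  fmat xcol;   // (C_in * ks) x (B * Lin)
  fmat act;    // nk x (B * Lin)   post-ReLU conv output
  fmat pooled; // nk x (B * Lout)
  umat pidx;   // argmax indices into act columns
  fmat dz;     // nk x (B * Lin)
  fmat dx;     // C_in x (B * Lin) gradient wrt layer input
  int Lin, Lout, Cin;
};

struct BranchWS {
  std::vector<LayerBuf> layer;
};

static void buildWS(BranchWS& ws, const NetConfig& c, int inLen, int B) {
  ws.layer.resize(c.depth);
  int L = inLen;
  for (int l = 0; l < c.depth; ++l) {
    LayerBuf& lb = ws.layer[l];
    lb.Cin = (l == 0) ? 1 : c.nk;
    lb.Lin = L;
    lb.Lout = L / c.pool;
    lb.xcol.set_size(lb.Cin * c.ks, B * L);
    lb.act.set_size(c.nk, B * L);
    lb.pooled.set_size(c.nk, B * lb.Lout);
    lb.pidx.set_size(c.nk, B * lb.Lout);
    lb.dz.set_size(c.nk, B * L);
    lb.dx.set_size(lb.Cin, B * L);
    L = lb.Lout;
  }
}

// forward through one branch for a batch laid out as X (1 x B*L);
// fills the workspace and leaves features in layer[depth-1].pooled
static void branchForwardBatch(const std::vector<fmat>& par, int off,
                               const NetConfig& c, BranchWS& ws,
                               const fmat& x0, int B) {
  const fmat* in = &x0;
  for (int l = 0; l < c.depth; ++l) {
    LayerBuf& lb = ws.layer[l];
    fmat xcol(lb.xcol.memptr(), lb.xcol.n_rows, (arma::uword) B * lb.Lin,
              false, true);
    for (int b = 0; b < B; ++b)
      im2colInto(*in, b * lb.Lin, lb.Lin, c.ks, true, xcol, b * lb.Lin);
    fmat act(lb.act.memptr(), c.nk, (arma::uword) B * lb.Lin, false, true);
    act = par[off + 2 * l] * xcol;
    act.each_col() += fvec(par[off + 2 * l + 1].col(0));
    reluInPlace(act);
    fmat pooled(lb.pooled.memptr(), c.nk, (arma::uword) B * lb.Lout,
                false, true);
    umat pidx(lb.pidx.memptr(), c.nk, (arma::uword) B * lb.Lout,
              false, true);
    maxpoolBatch(act, c.pool, c.pool, pooled, pidx);
    in = &lb.pooled;   // note: advanced-ctor views share lb memory
  }
}

// backward through one branch; dtop is nk x (B*Lf) gradient wrt the
// last pooled output; gradients accumulate into grad
static void branchBackwardBatch(const std::vector<fmat>& par, int off,
                                const NetConfig& c, BranchWS& ws,
                                fmat& dtop, int B,
                                std::vector<fmat>& grad) {
  fmat* dout = &dtop;            // gradient wrt layer l's pooled output
  for (int l = c.depth - 1; l >= 0; --l) {
    LayerBuf& lb = ws.layer[l];
    const arma::uword nIn = (arma::uword) B * lb.Lin;
    const arma::uword nOut = (arma::uword) B * lb.Lout;
    fmat dz(lb.dz.memptr(), c.nk, nIn, false, true);
    dz.zeros();
    // unpool + ReLU mask (pooled max > 0 <=> pre-ReLU > 0)
    for (arma::uword j = 0; j < nOut; ++j)
      for (int ch = 0; ch < c.nk; ++ch) {
        const arma::uword bi = lb.pidx(ch, j);
        if (lb.act(ch, bi) > 0.0f) dz(ch, bi) += (*dout)(ch, j);
      }
    fmat xcol(lb.xcol.memptr(), lb.xcol.n_rows, nIn, false, true);
    grad[off + 2 * l] += dz * xcol.t();
    grad[off + 2 * l + 1].col(0) += arma::sum(dz, 1);
    if (l > 0) {
      fmat dcol = par[off + 2 * l].t() * dz;
      fmat dx(lb.dx.memptr(), lb.Cin, nIn, false, true);
      for (int b = 0; b < B; ++b)
        col2imInto(dcol, b * lb.Lin, lb.Lin, lb.Cin, lb.Lin, c.ks, true,
                   dx, b * lb.Lin);
      dout = &lb.dx;
    }
  }
}

// gather per-sample flattened features of both branches into V (F x B)
static void gatherFeatures(const BranchWS& w1, const BranchWS& w2,
                           const NetConfig& c, int B, fmat& V) {
  const LayerBuf& t1 = w1.layer[c.depth - 1];
  const LayerBuf& t2 = w2.layer[c.depth - 1];
  const int half = c.nk * t1.Lout;
  for (int b = 0; b < B; ++b) {
    // column-major slab of one sample is contiguous
    std::memcpy(V.colptr(b),
                t1.pooled.colptr((arma::uword) b * t1.Lout),
                sizeof(float) * half);
    std::memcpy(V.colptr(b) + half,
                t2.pooled.colptr((arma::uword) b * t2.Lout),
                sizeof(float) * half);
  }
}

static void scatterFeatureGrad(const fmat& dV, const NetConfig& c, int B,
                               int Lf, fmat& d1, fmat& d2) {
  const int half = c.nk * Lf;
  for (int b = 0; b < B; ++b) {
    std::memcpy(d1.colptr((arma::uword) b * Lf), dV.colptr(b),
                sizeof(float) * half);
    std::memcpy(d2.colptr((arma::uword) b * Lf), dV.colptr(b) + half,
                sizeof(float) * half);
  }
}

// batched forward pass for inference
static fvec forwardBatch(const std::vector<fmat>& par, const NetConfig& c,
                         BranchWS& w1, BranchWS& w2,
                         const fmat& x1, const fmat& x2, int B, fmat& V) {
  const int headOff = 4 * c.depth;
  branchForwardBatch(par, 0, c, w1, x1, B);
  branchForwardBatch(par, 2 * c.depth, c, w2, x2, B);
  fmat Vv(V.memptr(), V.n_rows, B, false, true);
  gatherFeatures(w1, w2, c, B, Vv);
  fmat H = par[headOff] * Vv;
  H.each_col() += fvec(par[headOff + 1].col(0));
  reluInPlace(H);
  fvec o = (par[headOff + 2] * H).t() + par[headOff + 3](0, 0);
  for (int b = 0; b < B; ++b) o(b) = sigmoidf(o(b));
  return o;
}

// ---- training ------------------------------------------------------------

// [[Rcpp::export]]
List cpp_train(List weights, List cfgL,
               const arma::mat& pure_tr, const arma::mat& mix_tr,
               const arma::vec& y_tr,
               const arma::mat& pure_val, const arma::mat& mix_val,
               const arma::vec& y_val,
               int seed, bool verbose, bool best_epoch) {
  NetConfig c = parseConfig(cfgL);
  std::vector<fmat> par = weightsFromR(weights);
  fmat Ptr = arma::conv_to<fmat>::from(pure_tr);
  fmat Mtr = arma::conv_to<fmat>::from(mix_tr);
  fvec ytr = arma::conv_to<fvec>::from(y_tr);
  fmat Pva = arma::conv_to<fmat>::from(pure_val);
  fmat Mva = arma::conv_to<fmat>::from(mix_val);
  fvec yva = arma::conv_to<fvec>::from(y_val);
  const int n = Ptr.n_cols;
  const int L = Ptr.n_rows;
  const int nVal = Pva.n_cols;
  const int headOff = 4 * c.depth;
  const int B = std::min(c.batch, n);

  std::mt19937 gen((unsigned) seed);
  std::vector<fmat> grad, mAdam, vAdam;
  for (auto& p : par) {
    grad.emplace_back(p.n_rows, p.n_cols, arma::fill::zeros);
    mAdam.emplace_back(p.n_rows, p.n_cols, arma::fill::zeros);
    vAdam.emplace_back(p.n_rows, p.n_cols, arma::fill::zeros);
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  long tstep = 0;

  BranchWS w1, w2;
  buildWS(w1, c, L, B);
  buildWS(w2, c, L, B);
  int Lf = L;
  for (int l = 0; l < c.depth; ++l) Lf /= c.pool;
  const int F = 2 * c.nk * Lf;
  fmat X1(1, (arma::uword) B * L), X2(1, (arma::uword) B * L);
  fmat V(F, B), dtop1(c.nk, (arma::uword) B * Lf),
       dtop2(c.nk, (arma::uword) B * Lf);

  arma::mat hist(c.epochs, 4);
  hist.fill(arma::datum::nan);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::uniform_real_distribution<float> U(0.0f, 1.0f);
  const float clampEps = 1e-7f;
  std::vector<fmat> bestPar;
  double bestValAcc = -1.0;
  int bestEp = -1;

  for (int ep = 0; ep < c.epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), gen);
    double epLoss = 0.0, epOK = 0.0;
    for (int start = 0; start < n; start += B) {
      const int bs = std::min(B, n - start);
      // pack the batch along the length axis
      for (int k = 0; k < bs; ++k) {
        const int i = idx[start + k];
        std::memcpy(X1.colptr((arma::uword) k * L), Ptr.colptr(i),
                    sizeof(float) * L);
        std::memcpy(X2.colptr((arma::uword) k * L), Mtr.colptr(i),
                    sizeof(float) * L);
      }
      // forward
      branchForwardBatch(par, 0, c, w1, X1, bs);
      branchForwardBatch(par, 2 * c.depth, c, w2, X2, bs);
      fmat Vb(V.memptr(), F, bs, false, true);
      gatherFeatures(w1, w2, c, bs, Vb);
      fmat Z1 = par[headOff] * Vb;
      Z1.each_col() += fvec(par[headOff + 1].col(0));
      fmat H = Z1;
      reluInPlace(H);
      fmat keep(c.dense, bs, arma::fill::ones);
      if (c.dropout > 0.0f) {
        const float scale = 1.0f / (1.0f - c.dropout);
        float* kp = keep.memptr();
        for (arma::uword j = 0; j < keep.n_elem; ++j)
          kp[j] = (U(gen) < c.dropout) ? 0.0f : scale;
      }
      fmat Hd = H % keep;
      fvec o = (par[headOff + 2] * Hd).t() + par[headOff + 3](0, 0);
      fvec dlogit(bs);
      for (int k = 0; k < bs; ++k) {
        const float y = ytr(idx[start + k]);
        const float p = sigmoidf(o(k));
        const float pc = std::min(std::max(p, clampEps), 1.0f - clampEps);
        epLoss += -(y * std::log(pc) + (1.0f - y) * std::log(1.0f - pc));
        if ((p > 0.5f) == (y > 0.5f)) epOK += 1.0;
        dlogit(k) = p - y;
      }
      // backward (mean gradient over the batch)
      for (auto& g : grad) g.zeros();
      grad[headOff + 2] += dlogit.t() * Hd.t();
      grad[headOff + 3](0, 0) += arma::accu(dlogit);
      fmat dH = par[headOff + 2].t() * dlogit.t();   // dense x bs
      dH %= keep;
      // ReLU mask via pre-activation sign
      {
        float* dh = dH.memptr();
        const float* z1 = Z1.memptr();
        for (arma::uword j = 0; j < dH.n_elem; ++j)
          if (z1[j] <= 0.0f) dh[j] = 0.0f;
      }
      grad[headOff] += dH * Vb.t();
      grad[headOff + 1].col(0) += arma::sum(dH, 1);
      fmat dV = par[headOff].t() * dH;               // F x bs
      fmat d1(dtop1.memptr(), c.nk, (arma::uword) bs * Lf, false, true);
      fmat d2(dtop2.memptr(), c.nk, (arma::uword) bs * Lf, false, true);
      scatterFeatureGrad(dV, c, bs, Lf, d1, d2);
      branchBackwardBatch(par, 0, c, w1, d1, bs, grad);
      branchBackwardBatch(par, 2 * c.depth, c, w2, d2, bs, grad);

      // Adam step (single fused pass per parameter tensor)
      ++tstep;
      const float bc1 = 1.0f - std::pow(b1, (float) tstep);
      const float bc2 = 1.0f - std::pow(b2, (float) tstep);
      const float inv = 1.0f / (float) bs;
      const float sbc2 = std::sqrt(bc2);
      const float step = c.lr / bc1;
      for (size_t j = 0; j < par.size(); ++j) {
        float* g = grad[j].memptr();
        float* m = mAdam[j].memptr();
        float* v = vAdam[j].memptr();
        float* p = par[j].memptr();
        const arma::uword ne = par[j].n_elem;
        for (arma::uword e = 0; e < ne; ++e) {
          const float ge = g[e] * inv;
          m[e] = b1 * m[e] + (1.0f - b1) * ge;
          v[e] = b2 * v[e] + (1.0f - b2) * ge * ge;
          p[e] -= step * m[e] / (std::sqrt(v[e]) / sbc2 + eps);
        }
      }
      Rcpp::checkUserInterrupt();
    }
    hist(ep, 0) = epLoss / (double) n;
    hist(ep, 1) = epOK / (double) n;
    if (nVal > 0) {
      double vl = 0.0, vok = 0.0;
      for (int start = 0; start < nVal; start += B) {
        const int bs = std::min(B, nVal - start);
        for (int k = 0; k < bs; ++k) {
          std::memcpy(X1.colptr((arma::uword) k * L), Pva.colptr(start + k),
                      sizeof(float) * L);
          std::memcpy(X2.colptr((arma::uword) k * L), Mva.colptr(start + k),
                      sizeof(float) * L);
        }
        fvec o = forwardBatch(par, c, w1, w2, X1, X2, bs, V);
        for (int k = 0; k < bs; ++k) {
          const float y = yva(start + k);
          const float pc = std::min(std::max(o(k), clampEps),
                                    1.0f - clampEps);
          vl += -(y * std::log(pc) + (1.0f - y) * std::log(1.0f - pc));
          if ((o(k) > 0.5f) == (y > 0.5f)) vok += 1.0;
        }
      }
      hist(ep, 2) = vl / (double) nVal;
      hist(ep, 3) = vok / (double) nVal;
      if (best_epoch && hist(ep, 3) > bestValAcc) {
        bestValAcc = hist(ep, 3);
        bestPar = par;
        bestEp = ep + 1;
      }
    }
    if (verbose)
      Rprintf("epoch %3d/%d  loss %.4f  acc %.4f  val_loss %.4f  val_acc %.4f\n",
              ep + 1, c.epochs, hist(ep, 0), hist(ep, 1), hist(ep, 2),
              hist(ep, 3));
  }
  const bool useBest = best_epoch && bestEp > 0;
  return List::create(
      _["weights"] = weightsToR(useBest ? bestPar : par, c),
      _["history"] = wrap(hist),
      _["bestEpoch"] = useBest ? bestEp : NA_INTEGER);
}

// [[Rcpp::export]]
NumericVector cpp_predict(List weights, List cfgL,
                          const arma::mat& pure, const arma::mat& mix) {
  NetConfig c = parseConfig(cfgL);
  std::vector<fmat> par = weightsFromR(weights);
  fmat P = arma::conv_to<fmat>::from(pure);
  fmat M = arma::conv_to<fmat>::from(mix);
  const int n = P.n_cols;
  const int L = P.n_rows;
  const int B = std::min(std::max(c.batch, 1), std::max(n, 1));
  BranchWS w1, w2;
  buildWS(w1, c, L, B);
  buildWS(w2, c, L, B);
  int Lf = L;
  for (int l = 0; l < c.depth; ++l) Lf /= c.pool;
  fmat X1(1, (arma::uword) B * L), X2(1, (arma::uword) B * L);
  fmat V(2 * c.nk * Lf, B);
  NumericVector out(n);
  for (int start = 0; start < n; start += B) {
    const int bs = std::min(B, n - start);
    for (int k = 0; k < bs; ++k) {
      std::memcpy(X1.colptr((arma::uword) k * L), P.colptr(start + k),
                  sizeof(float) * L);
      std::memcpy(X2.colptr((arma::uword) k * L), M.colptr(start + k),
                  sizeof(float) * L);
    }
    fvec o = forwardBatch(par, c, w1, w2, X1, X2, bs, V);
    for (int k = 0; k < bs; ++k) out[start + k] = (double) o(k);
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---- exposed primitives (same kernels the model uses) --------------------

// x: C x L; W: cube n_out x C x ks; ReLU applied when relu_act
// [[Rcpp::export]]
NumericMatrix cpp_conv1d(const arma::mat& x, const arma::cube& W,
                         const arma::vec& bias, bool same, bool relu_act) {
  const int C = x.n_rows, ks = W.n_slices, nOut = W.n_rows;
  const int L = x.n_cols;
  if ((int) W.n_cols != C) stop("kernel channel count does not match input");
  fmat xf = arma::conv_to<fmat>::from(x);
  fmat Wm(nOut, C * ks);
  for (int t = 0; t < ks; ++t)
    for (int cc = 0; cc < C; ++cc)
      for (int o = 0; o < nOut; ++o)
        Wm(o, t * C + cc) = (float) W(o, cc, t);
  const int Lo = same ? L : L - ks + 1;
  fmat xcol(C * ks, Lo, arma::fill::zeros);
  im2colInto(xf, 0, L, ks, same, xcol, 0);
  fmat z = Wm * xcol;
  z.each_col() += arma::conv_to<fvec>::from(bias);
  if (relu_act) reluInPlace(z);
  return wrap(arma::conv_to<arma::mat>::from(z));
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool1d(const arma::mat& x, int size, int stride) {
  fmat xf = arma::conv_to<fmat>::from(x);
  const int Lo = ((int) x.n_cols >= size)
                   ? ((int) x.n_cols - size) / stride + 1 : 0;
  fmat p(x.n_rows, Lo);
  // generic strided variant for the exposed primitive
  for (int j = 0; j < Lo; ++j) {
    const int s = j * stride;
    for (arma::uword c = 0; c < x.n_rows; ++c) {
      float best = xf(c, s);
      for (int t = 1; t < size; ++t) best = std::max(best, xf(c, s + t));
      p(c, j) = best;
    }
  }
  return wrap(arma::conv_to<arma::mat>::from(p));
}
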