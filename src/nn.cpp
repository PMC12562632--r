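// Float32 forward/backward/Adam engine for the three spectral regressors
// (multiscale CNN, multiscale CNN + single-step LSTM head, 1-D ResNet18).
// Convolutions are evaluated tap-wise as dense GEMMs on a (channels x
// length*batch) activation layout with sample-major column blocks, so the
// heavy lifting stays in BLAS. All randomness (init, shuffles, validation
// holdout) flows from an explicit seed through a private mt19937 stream,
// making training bitwise reproducible on a single thread.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>
#include <random>
#include <string>
#include <vector>

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

namespace {

struct RNG {
  std::mt19937 g;
  bool hasSpare = false;
  double spare = 0.0;
  explicit RNG(uint32_t s) : g(s) {}
  double unif() { return g() * (1.0 / 4294967296.0); }
  double unif(double a, double b) { return a + (b - a) * unif(); }
  int upto(int n) { return static_cast<int>(g() % static_cast<uint32_t>(n)); }
  void shuffle(std::vector<int>& v) {
    for (int i = static_cast<int>(v.size()) - 1; i > 0; --i)
      std::swap(v[i], v[upto(i + 1)]);
  }
};

constexpr float BN_EPS = 1e-5f;
constexpr float BN_MOM = 0.1f;

// ---------------------------------------------------------------- tensors

struct Tensor {
  std::string name;
  fmat v, g, m, w2;          // value, grad, Adam moments
  int initType = 0;          // 0: U(+-1/sqrt(fanIn)), 1: constant
  double initA = 1.0;        // fanIn or the constant
  std::vector<int> rdim;     // dims for the R-side array (empty: matrix)
};

struct Net {
  std::vector<Tensor> ps;    // trainable
  std::vector<Tensor> st;    // batch-norm running stats
  std::map<std::string, int> pi, si;
  long step = 0;

  fmat& P(const std::string& n) { return ps[pi.at(n)].v; }
  fmat& G(const std::string& n) { return ps[pi.at(n)].g; }
  fmat& S(const std::string& n) { return st[si.at(n)].v; }

  void addP(const std::string& n, int r, int c, int it, double a,
            std::vector<int> rd = {}) {
    Tensor t;
    t.name = n;
    t.v.zeros(r, c); t.g.zeros(r, c); t.m.zeros(r, c); t.w2.zeros(r, c);
    t.initType = it; t.initA = a; t.rdim = rd;
    pi[n] = static_cast<int>(ps.size());
    ps.push_back(std::move(t));
  }
  void addS(const std::string& n, int r, double val) {
    Tensor t;
    t.name = n;
    t.v.set_size(r, 1);
    t.v.fill(static_cast<float>(val));
    t.initA = val;
    si[n] = static_cast<int>(st.size());
    st.push_back(std::move(t));
  }
  void addBN(const std::string& pre, int C) {
    addP(pre + ".gamma", C, 1, 1, 1.0);
    addP(pre + ".beta", C, 1, 1, 0.0);
    addS(pre + ".runMean", C, 0.0);
    addS(pre + ".runVar", C, 1.0);
  }
  void init(uint32_t seed) {
    RNG rng(seed);
    for (auto& t : ps) {
      if (t.initType == 1) {
        t.v.fill(static_cast<float>(t.initA));
      } else {
        double b = 1.0 / std::sqrt(t.initA);
        for (uword i = 0; i < t.v.n_elem; ++i)
          t.v[i] = static_cast<float>(rng.unif(-b, b));
      }
      t.m.zeros(); t.w2.zeros();
    }
    for (auto& t : st) t.v.fill(static_cast<float>(t.initA));
    step = 0;
  }
  void zeroGrad() { for (auto& t : ps) t.g.zeros(); }
};

// ------------------------------------------------------------ layer ops

struct ConvG { int Cin, Cout, k, s, p, Lin, Lout, N; };

struct ConvCache {
  fmat Xcol;      // im2col matrix (Cin*k x Lout*N)
  fmat Xp, dXp, dXcol;  // persistent scratch (avoids per-batch reallocation)
  uvec base;      // column of the padded input for tap 0 of each position
  ConvG g;
};

inline int outLen(int L, int k, int s, int p) {
  return (L + 2 * p - k) / s + 1;
}

// im2col + single GEMM; W is (Cout x Cin*k), tap-major column blocks
fmat conv_fwd(const fmat& X, const fmat& W, const fmat& b, ConvG g,
              ConvCache& cc) {
  const int Lp = g.Lin + 2 * g.p;
  cc.g = g;
  fmat& Xp = cc.Xp;
  Xp.zeros(g.Cin, static_cast<size_t>(Lp) * g.N);
  for (int n = 0; n < g.N; ++n)
    std::memcpy(Xp.colptr(static_cast<size_t>(n) * Lp + g.p),
                X.colptr(static_cast<size_t>(n) * g.Lin),
                sizeof(float) * g.Cin * g.Lin);
  const size_t M = static_cast<size_t>(g.Lout) * g.N;
  cc.base.set_size(M);
  for (int n = 0; n < g.N; ++n)
    for (int j = 0; j < g.Lout; ++j)
      cc.base[static_cast<size_t>(n) * g.Lout + j] =
          static_cast<size_t>(n) * Lp + static_cast<size_t>(j) * g.s;
  cc.Xcol.set_size(static_cast<size_t>(g.Cin) * g.k, M);
  for (size_t j = 0; j < M; ++j) {
    float* dst = cc.Xcol.colptr(j);
    const float* src = Xp.colptr(cc.base[j]);
    std::memcpy(dst, src, sizeof(float) * g.Cin * g.k);  // taps are adjacent cols
  }
  fmat Y = W * cc.Xcol;
  const float* bp = b.memptr();
  for (size_t j = 0; j < M; ++j) {
    float* yp = Y.colptr(j);
    for (int c = 0; c < g.Cout; ++c) yp[c] += bp[c];
  }
  return Y;
}

fmat conv_bwd(const fmat& dY, const fmat& W, fmat& dW, fmat& db,
              ConvCache& cc) {
  const ConvG g = cc.g;
  const int Lp = g.Lin + 2 * g.p;
  db.col(0) += sum(dY, 1);
  dW += dY * cc.Xcol.t();
  fmat& dXcol = cc.dXcol;
  dXcol = W.t() * dY;
  fmat& dXp = cc.dXp;
  dXp.zeros(g.Cin, static_cast<size_t>(Lp) * g.N);
  const int span = g.Cin * g.k;
  for (uword j = 0; j < cc.base.n_elem; ++j) {
    float* dst = dXp.colptr(cc.base[j]);
    const float* src = dXcol.colptr(j);
    for (int i = 0; i < span; ++i) dst[i] += src[i];
  }
  fmat dX(g.Cin, static_cast<size_t>(g.Lin) * g.N);
  for (int n = 0; n < g.N; ++n)
    std::memcpy(dX.colptr(static_cast<size_t>(n) * g.Lin),
                dXp.colptr(static_cast<size_t>(n) * Lp + g.p),
                sizeof(float) * g.Cin * g.Lin);
  return dX;
}

struct BNCache { fmat xhat; fvec invstd; int M = 0; };

// in-place batch norm; caches xhat for the backward pass
void bn_fwd(fmat& X, const fmat& gamma, const fmat& beta, fmat& rm,
            fmat& rv, bool train, BNCache& bc) {
  const int C = X.n_rows;
  const size_t M = X.n_cols;
  if (train) {
    std::vector<double> s(C, 0.0), s2(C, 0.0);
    for (size_t j = 0; j < M; ++j) {
      const float* xp = X.colptr(j);
      for (int c = 0; c < C; ++c) { s[c] += xp[c]; s2[c] += (double)xp[c] * xp[c]; }
    }
    fvec mu(C), var(C);
    for (int c = 0; c < C; ++c) {
      mu[c] = static_cast<float>(s[c] / M);
      var[c] = static_cast<float>(s2[c] / M - (s[c] / M) * (s[c] / M));
      if (var[c] < 0.0f) var[c] = 0.0f;
    }
    bc.invstd = 1.0f / sqrt(var + BN_EPS);
    bc.M = static_cast<int>(M);
    rm.col(0) = (1.0f - BN_MOM) * rm.col(0) + BN_MOM * mu;
    rv.col(0) = (1.0f - BN_MOM) * rv.col(0) + BN_MOM * var;
    bc.xhat.set_size(C, M);
    const float* gp = gamma.memptr();
    const float* bp = beta.memptr();
    for (size_t j = 0; j < M; ++j) {
      const float* xp = X.colptr(j);
      float* hp = bc.xhat.colptr(j);
      float* yp = X.colptr(j);
      for (int c = 0; c < C; ++c) {
        const float h = (xp[c] - mu[c]) * bc.invstd[c];
        hp[c] = h;
        yp[c] = gp[c] * h + bp[c];
      }
    }
  } else {
    fvec scale = gamma.col(0) / sqrt(rv.col(0) + BN_EPS);
    fvec shift = beta.col(0) - rm.col(0) % scale;
    const float* sc = scale.memptr();
    const float* sh = shift.memptr();
    for (size_t j = 0; j < M; ++j) {
      float* xp = X.colptr(j);
      for (int c = 0; c < C; ++c) xp[c] = sc[c] * xp[c] + sh[c];
    }
  }
}

// consumes dY in place and returns it as dX
fmat bn_bwd(fmat dY, const fmat& gamma, fmat& dgamma, fmat& dbeta,
            BNCache& bc) {
  const int C = dY.n_rows;
  const size_t M = dY.n_cols;
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  for (size_t j = 0; j < M; ++j) {
    const float* dp = dY.colptr(j);
    const float* hp = bc.xhat.colptr(j);
    for (int c = 0; c < C; ++c) { s1[c] += dp[c]; s2[c] += (double)dp[c] * hp[c]; }
  }
  const float* gp = gamma.memptr();
  fvec a1(C), a2(C);
  for (int c = 0; c < C; ++c) {
    dbeta(c, 0) += static_cast<float>(s1[c]);
    dgamma(c, 0) += static_cast<float>(s2[c]);
    a1[c] = static_cast<float>(s1[c] / bc.M);
    a2[c] = static_cast<float>(s2[c] / bc.M);
  }
  for (size_t j = 0; j < M; ++j) {
    float* dp = dY.colptr(j);
    const float* hp = bc.xhat.colptr(j);
    for (int c = 0; c < C; ++c)
      dp[c] = (gp[c] * dp[c] - gp[c] * a1[c] - gp[c] * hp[c] * a2[c]) *
              bc.invstd[c];
  }
  return dY;
}

// in-place ReLU, mask cached as floats
void relu_fwd(fmat& X, fmat& mask) {
  mask.set_size(X.n_rows, X.n_cols);
  float* xp = X.memptr();
  float* mp = mask.memptr();
  const size_t n = X.n_elem;
  for (size_t i = 0; i < n; ++i) {
    const float m = xp[i] > 0.0f ? 1.0f : 0.0f;
    mp[i] = m;
    xp[i] *= m;
  }
}

struct PoolCache { Mat<uword> src; int Lin = 0, Lout = 0, N = 0, C = 0; };

fmat pool_fwd(const fmat& X, int C, int Lin, int N, int k, int s, int p,
              PoolCache& pc) {
  const int Lout = outLen(Lin, k, s, p);
  pc.Lin = Lin; pc.Lout = Lout; pc.N = N; pc.C = C;
  fmat Y(C, static_cast<size_t>(Lout) * N);
  Y.fill(-1e30f);
  pc.src.set_size(C, static_cast<size_t>(Lout) * N);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < Lout; ++j) {
      const size_t oc = static_cast<size_t>(n) * Lout + j;
      const int start = j * s - p;
      for (int t = 0; t < k; ++t) {
        const int pos = start + t;
        if (pos < 0 || pos >= Lin) continue;
        const size_t ic = static_cast<size_t>(n) * Lin + pos;
        for (int c = 0; c < C; ++c) {
          const float v = X(c, ic);
          if (v > Y(c, oc)) { Y(c, oc) = v; pc.src(c, oc) = ic; }
        }
      }
    }
  return Y;
}

fmat pool_bwd(const fmat& dY, PoolCache& pc) {
  fmat dX(pc.C, static_cast<size_t>(pc.Lin) * pc.N, fill::zeros);
  for (uword j = 0; j < dY.n_cols; ++j)
    for (int c = 0; c < pc.C; ++c)
      dX(c, pc.src(c, j)) += dY(c, j);
  return dX;
}

fmat fc_fwd(const fmat& X, const fmat& W, const fmat& b) {
  fmat Y = W * X;
  Y.each_col() += b.col(0);
  return Y;
}

struct LSTMCache { fmat x, i, f, g, o, c, tc; };

fmat lstm_fwd(const fmat& x, const fmat& Wih, const fmat& bih,
              const fmat& bhh, int H, LSTMCache& lc) {
  // single step, h0 = c0 = 0: the recurrent term W_hh h0 vanishes
  fmat gates = Wih * x;
  gates.each_col() += (bih.col(0) + bhh.col(0));
  lc.x = x;
  lc.i = 1.0f / (1.0f + exp(-gates.rows(0, H - 1)));
  lc.f = 1.0f / (1.0f + exp(-gates.rows(H, 2 * H - 1)));
  lc.g = tanh(gates.rows(2 * H, 3 * H - 1));
  lc.o = 1.0f / (1.0f + exp(-gates.rows(3 * H, 4 * H - 1)));
  lc.c = lc.i % lc.g;
  lc.tc = tanh(lc.c);
  return lc.o % lc.tc;
}

fmat lstm_bwd(const fmat& dh, const fmat& Wih, fmat& dWih, fmat& dbih,
              fmat& dbhh, int H, LSTMCache& lc) {
  fmat dO = dh % lc.tc % lc.o % (1.0f - lc.o);
  fmat dC = dh % lc.o % (1.0f - square(lc.tc));
  fmat dI = dC % lc.g % lc.i % (1.0f - lc.i);
  fmat dG = dC % lc.i % (1.0f - square(lc.g));
  fmat dF(H, dh.n_cols, fill::zeros);  // c0 = 0: forget gate gets no signal
  fmat dgates = join_cols(join_cols(dI, dF), join_cols(dG, dO));
  dWih += dgates * lc.x.t();
  fvec s = sum(dgates, 1);
  dbih.col(0) += s;
  dbhh.col(0) += s;  // W_hh multiplies h0 = 0: zero gradient, left untouched
  return Wih.t() * dgates;
}

// ------------------------------------------------------------- MSCNN

struct MCfg {
  int L, Cout, stride, poolK, poolS, fcH, hidden;
  int k[3], c1[3], pad[3];
  bool lstm;
  int L1, L2, Lp, flat;
};

MCfg readMCfg(const List& cfg, const std::string& arch) {
  MCfg c;
  c.L = Rcpp::as<int>(cfg["inputLength"]);
  Rcpp::IntegerVector ks = cfg["kernels"], c1 = cfg["channels1"],
                      pd = cfg["paddings"];
  for (int b = 0; b < 3; ++b) { c.k[b] = ks[b]; c.c1[b] = c1[b]; c.pad[b] = pd[b]; }
  c.Cout = Rcpp::as<int>(cfg["outChannels"]);
  c.stride = Rcpp::as<int>(cfg["stride"]);
  c.poolK = Rcpp::as<int>(cfg["poolKernel"]);
  c.poolS = Rcpp::as<int>(cfg["poolStride"]);
  c.fcH = Rcpp::as<int>(cfg["fcHidden"]);
  c.hidden = Rcpp::as<int>(cfg["lstmHidden"]);
  c.lstm = (arch == "mscnn_lstm");
  c.L1 = outLen(c.L, c.k[0], c.stride, c.pad[0]);
  c.L2 = outLen(c.L1, c.k[0], c.stride, c.pad[0]);
  c.Lp = outLen(c.L2, c.poolK, c.poolS, 0);
  c.flat = c.Cout * c.Lp;
  return c;
}

void registerMscnn(Net& net, const MCfg& c) {
  for (int b = 0; b < 3; ++b) {
    std::string pre = "branch" + std::to_string(b + 1) + ".";
    net.addP(pre + "conv1.W", c.c1[b], c.k[b], 0, c.k[b], {c.c1[b], 1, c.k[b]});
    net.addP(pre + "conv1.b", c.c1[b], 1, 0, c.k[b]);
    net.addBN(pre + "bn1", c.c1[b]);
    net.addP(pre + "conv2.W", c.Cout, c.c1[b] * c.k[b], 0,
             static_cast<double>(c.c1[b]) * c.k[b], {c.Cout, c.c1[b], c.k[b]});
    net.addP(pre + "conv2.b", c.Cout, 1, 0, static_cast<double>(c.c1[b]) * c.k[b]);
    net.addBN(pre + "bn2", c.Cout);
  }
  for (int b = 0; b < 3; ++b)
    net.addP("fusion.w" + std::to_string(b + 1), c.Cout, 1, 1, 1.0 / 3.0);
  net.addP("fc1.W", c.fcH, c.flat, 0, c.flat);
  net.addP("fc1.b", c.fcH, 1, 0, c.flat);
  if (c.lstm) {
    net.addP("lstm.W_ih", 4 * c.hidden, c.fcH, 0, c.hidden);
    net.addP("lstm.W_hh", 4 * c.hidden, c.hidden, 0, c.hidden);
    net.addP("lstm.b_ih", 4 * c.hidden, 1, 0, c.hidden);
    net.addP("lstm.b_hh", 4 * c.hidden, 1, 0, c.hidden);
    net.addP("head.W", 1, c.hidden, 0, c.hidden);
    net.addP("head.b", 1, 1, 0, c.hidden);
  } else {
    net.addP("head.W", 1, c.fcH, 0, c.fcH);
    net.addP("head.b", 1, 1, 0, c.fcH);
  }
}

struct MBranchCache {
  ConvCache c1, c2;
  BNCache b1, b2;
  fmat m1, m2, F;
  PoolCache pl;
};

struct MCache {
  MBranchCache br[3];
  fmat Ffused, fc1in, fc1mask, H, H2;
  LSTMCache lc;
  int N = 0;
};

fmat mscnn_fwd(Net& net, const MCfg& c, const fmat& X, int N, bool train,
               MCache& mc) {
  mc.N = N;
  for (int b = 0; b < 3; ++b) {
    auto& B = mc.br[b];
    std::string pre = "branch" + std::to_string(b + 1) + ".";
    ConvG g1{1, c.c1[b], c.k[b], c.stride, c.pad[b], c.L, c.L1, N};
    fmat a = conv_fwd(X, net.P(pre + "conv1.W"), net.P(pre + "conv1.b"), g1, B.c1);
    bn_fwd(a, net.P(pre + "bn1.gamma"), net.P(pre + "bn1.beta"),
           net.S(pre + "bn1.runMean"), net.S(pre + "bn1.runVar"), train, B.b1);
    relu_fwd(a, B.m1);
    ConvG g2{c.c1[b], c.Cout, c.k[b], c.stride, c.pad[b], c.L1, c.L2, N};
    a = conv_fwd(a, net.P(pre + "conv2.W"), net.P(pre + "conv2.b"), g2, B.c2);
    bn_fwd(a, net.P(pre + "bn2.gamma"), net.P(pre + "bn2.beta"),
           net.S(pre + "bn2.runMean"), net.S(pre + "bn2.runVar"), train, B.b2);
    relu_fwd(a, B.m2);
    B.F = pool_fwd(a, c.Cout, c.L2, N, c.poolK, c.poolS, 0, B.pl);
  }
  mc.Ffused = mc.br[0].F.each_col() % net.P("fusion.w1").col(0);
  mc.Ffused += mc.br[1].F.each_col() % net.P("fusion.w2").col(0);
  mc.Ffused += mc.br[2].F.each_col() % net.P("fusion.w3").col(0);
  mc.fc1in = reshape(mc.Ffused, c.flat, N);
  mc.H = fc_fwd(mc.fc1in, net.P("fc1.W"), net.P("fc1.b"));
  relu_fwd(mc.H, mc.fc1mask);
  mc.H2 = c.lstm
    ? lstm_fwd(mc.H, net.P("lstm.W_ih"), net.P("lstm.b_ih"),
               net.P("lstm.b_hh"), c.hidden, mc.lc)
    : mc.H;
  return fc_fwd(mc.H2, net.P("head.W"), net.P("head.b"));
}

void mscnn_bwd(Net& net, const MCfg& c, const fmat& dY, MCache& mc) {
  // head
  net.G("head.W") += dY * mc.H2.t();
  net.G("head.b").col(0) += sum(dY, 1);
  fmat dH2 = net.P("head.W").t() * dY;
  fmat dH = c.lstm
    ? lstm_bwd(dH2, net.P("lstm.W_ih"), net.G("lstm.W_ih"),
               net.G("lstm.b_ih"), net.G("lstm.b_hh"), c.hidden, mc.lc)
    : dH2;
  dH %= mc.fc1mask;
  net.G("fc1.W") += dH * mc.fc1in.t();
  net.G("fc1.b").col(0) += sum(dH, 1);
  fmat dFlat = net.P("fc1.W").t() * dH;
  fmat dF = reshape(dFlat, c.Cout, static_cast<size_t>(c.Lp) * mc.N);
  for (int b = 0; b < 3; ++b) {
    auto& B = mc.br[b];
    std::string w = "fusion.w" + std::to_string(b + 1);
    net.G(w).col(0) += sum(dF % B.F, 1);
    fmat dFb = dF.each_col() % net.P(w).col(0);
    dFb = pool_bwd(dFb, B.pl);
    dFb %= B.m2;
    std::string pre = "branch" + std::to_string(b + 1) + ".";
    dFb = bn_bwd(dFb, net.P(pre + "bn2.gamma"), net.G(pre + "bn2.gamma"),
                 net.G(pre + "bn2.beta"), B.b2);
    dFb = conv_bwd(dFb, net.P(pre + "conv2.W"), net.G(pre + "conv2.W"),
                   net.G(pre + "conv2.b"), B.c2);
    dFb %= B.m1;
    dFb = bn_bwd(dFb, net.P(pre + "bn1.gamma"), net.G(pre + "bn1.gamma"),
                 net.G(pre + "bn1.beta"), B.b1);
    conv_bwd(dFb, net.P(pre + "conv1.W"), net.G(pre + "conv1.W"),
             net.G(pre + "conv1.b"), B.c1);
  }
}

// ------------------------------------------------------------- ResNet18

struct RCfg {
  int L;
  int ch[4] = {64, 128, 256, 512};
  int Lstem, Lpool;
  int lens[4];
};

RCfg readRCfg(const List& cfg) {
  RCfg c;
  c.L = Rcpp::as<int>(cfg["inputLength"]);
  c.Lstem = outLen(c.L, 7, 2, 3);
  c.Lpool = outLen(c.Lstem, 3, 2, 1);
  int L = c.Lpool;
  for (int g = 0; g < 4; ++g) {
    if (g > 0) L = outLen(L, 3, 2, 1);
    c.lens[g] = L;
  }
  return c;
}

void registerResnet(Net& net, const RCfg& c) {
  net.addP("stem.conv.W", 64, 7, 0, 7, {64, 1, 7});
  net.addP("stem.conv.b", 64, 1, 0, 7);
  net.addBN("stem.bn", 64);
  for (int g = 0; g < 4; ++g)
    for (int i = 0; i < 2; ++i) {
      const int inCh = (i == 0) ? (g == 0 ? 64 : c.ch[g - 1]) : c.ch[g];
      std::string pre = "group" + std::to_string(g + 1) + ".block" +
                        std::to_string(i + 1) + ".";
      net.addP(pre + "conv1.W", c.ch[g], inCh * 3, 0,
               static_cast<double>(inCh) * 3, {c.ch[g], inCh, 3});
      net.addP(pre + "conv1.b", c.ch[g], 1, 0, static_cast<double>(inCh) * 3);
      net.addBN(pre + "bn1", c.ch[g]);
      net.addP(pre + "conv2.W", c.ch[g], c.ch[g] * 3, 0,
               static_cast<double>(c.ch[g]) * 3, {c.ch[g], c.ch[g], 3});
      net.addP(pre + "conv2.b", c.ch[g], 1, 0, static_cast<double>(c.ch[g]) * 3);
      net.addBN(pre + "bn2", c.ch[g]);
      if (i == 0 && g > 0) {  // channel/stride change: 1x1 projection
        net.addP(pre + "proj.W", c.ch[g], inCh, 0, inCh, {c.ch[g], inCh, 1});
        net.addP(pre + "proj.b", c.ch[g], 1, 0, inCh);
        net.addBN(pre + "bnp", c.ch[g]);
      }
    }
  net.addP("head.W", 1, 512, 0, 512);
  net.addP("head.b", 1, 1, 0, 512);
}

struct RBlockCache {
  ConvCache c1, c2, cp;
  BNCache b1, b2, bp;
  fmat m1, mout, skipIn;
  bool hasProj = false;
  int inCh = 0, outCh = 0, Lin = 0, Lout = 0;
};

struct RCache {
  ConvCache stem;
  BNCache stembn;
  fmat stemMask;
  PoolCache stemPool;
  RBlockCache blk[4][2];
  fmat feat;   // pre-GAP activations (512 x len*N)
  int N = 0;
};

fmat resnet_fwd(Net& net, const RCfg& c, const fmat& X, int N, bool train,
                RCache& rc) {
  rc.N = N;
  ConvG gs{1, 64, 7, 2, 3, c.L, c.Lstem, N};
  fmat a = conv_fwd(X, net.P("stem.conv.W"), net.P("stem.conv.b"), gs, rc.stem);
  bn_fwd(a, net.P("stem.bn.gamma"), net.P("stem.bn.beta"),
         net.S("stem.bn.runMean"), net.S("stem.bn.runVar"), train, rc.stembn);
  relu_fwd(a, rc.stemMask);
  a = pool_fwd(a, 64, c.Lstem, N, 3, 2, 1, rc.stemPool);
  for (int g = 0; g < 4; ++g)
    for (int i = 0; i < 2; ++i) {
      auto& B = rc.blk[g][i];
      B.inCh = (i == 0) ? (g == 0 ? 64 : c.ch[g - 1]) : c.ch[g];
      B.outCh = c.ch[g];
      const int stride = (i == 0 && g > 0) ? 2 : 1;
      B.Lin = (i == 0) ? (g == 0 ? c.Lpool : c.lens[g - 1]) : c.lens[g];
      B.Lout = c.lens[g];
      B.hasProj = (i == 0 && g > 0);
      std::string pre = "group" + std::to_string(g + 1) + ".block" +
                        std::to_string(i + 1) + ".";
      B.skipIn = a;
      ConvG g1{B.inCh, B.outCh, 3, stride, 1, B.Lin, B.Lout, N};
      fmat m = conv_fwd(a, net.P(pre + "conv1.W"), net.P(pre + "conv1.b"), g1, B.c1);
      bn_fwd(m, net.P(pre + "bn1.gamma"), net.P(pre + "bn1.beta"),
             net.S(pre + "bn1.runMean"), net.S(pre + "bn1.runVar"), train, B.b1);
      relu_fwd(m, B.m1);
      ConvG g2{B.outCh, B.outCh, 3, 1, 1, B.Lout, B.Lout, N};
      m = conv_fwd(m, net.P(pre + "conv2.W"), net.P(pre + "conv2.b"), g2, B.c2);
      bn_fwd(m, net.P(pre + "bn2.gamma"), net.P(pre + "bn2.beta"),
             net.S(pre + "bn2.runMean"), net.S(pre + "bn2.runVar"), train, B.b2);
      if (B.hasProj) {
        ConvG gp{B.inCh, B.outCh, 1, stride, 0, B.Lin, B.Lout, N};
        fmat skip = conv_fwd(a, net.P(pre + "proj.W"), net.P(pre + "proj.b"), gp, B.cp);
        bn_fwd(skip, net.P(pre + "bnp.gamma"), net.P(pre + "bnp.beta"),
               net.S(pre + "bnp.runMean"), net.S(pre + "bnp.runVar"),
               train, B.bp);
        m += skip;
      } else {
        m += a;
      }
      relu_fwd(m, B.mout);
      a = std::move(m);
    }
  rc.feat = a;
  // global average pooling to (512, N)
  fmat pooled(512, N);
  const int L = c.lens[3];
  for (int n = 0; n < N; ++n)
    pooled.col(n) = mean(a.cols(static_cast<size_t>(n) * L,
                                static_cast<size_t>(n + 1) * L - 1), 1);
  return fc_fwd(pooled, net.P("head.W"), net.P("head.b"));
}

void resnet_bwd(Net& net, const RCfg& c, const fmat& dY, RCache& rc) {
  const int N = rc.N;
  const int L = c.lens[3];
  fmat pooled(512, N);
  for (int n = 0; n < N; ++n)
    pooled.col(n) = mean(rc.feat.cols(static_cast<size_t>(n) * L,
                                      static_cast<size_t>(n + 1) * L - 1), 1);
  net.G("head.W") += dY * pooled.t();
  net.G("head.b").col(0) += sum(dY, 1);
  fmat dPooled = net.P("head.W").t() * dY;
  fmat da(512, static_cast<size_t>(L) * N);
  for (int n = 0; n < N; ++n)
    da.cols(static_cast<size_t>(n) * L, static_cast<size_t>(n + 1) * L - 1) =
        repmat(dPooled.col(n) / static_cast<float>(L), 1, L);
  for (int g = 3; g >= 0; --g)
    for (int i = 1; i >= 0; --i) {
      auto& B = rc.blk[g][i];
      std::string pre = "group" + std::to_string(g + 1) + ".block" +
                        std::to_string(i + 1) + ".";
      da %= B.mout;
      fmat dmain = da;
      fmat dskip = da;
      dmain = bn_bwd(dmain, net.P(pre + "bn2.gamma"), net.G(pre + "bn2.gamma"),
                     net.G(pre + "bn2.beta"), B.b2);
      dmain = conv_bwd(dmain, net.P(pre + "conv2.W"), net.G(pre + "conv2.W"),
                       net.G(pre + "conv2.b"), B.c2);
      dmain %= B.m1;
      dmain = bn_bwd(dmain, net.P(pre + "bn1.gamma"), net.G(pre + "bn1.gamma"),
                     net.G(pre + "bn1.beta"), B.b1);
      dmain = conv_bwd(dmain, net.P(pre + "conv1.W"), net.G(pre + "conv1.W"),
                       net.G(pre + "conv1.b"), B.c1);
      if (B.hasProj) {
        dskip = bn_bwd(dskip, net.P(pre + "bnp.gamma"), net.G(pre + "bnp.gamma"),
                       net.G(pre + "bnp.beta"), B.bp);
        dskip = conv_bwd(dskip, net.P(pre + "proj.W"), net.G(pre + "proj.W"),
                         net.G(pre + "proj.b"), B.cp);
      }
      da = dmain + dskip;
    }
  da = pool_bwd(da, rc.stemPool);
  da %= rc.stemMask;
  da = bn_bwd(da, net.P("stem.bn.gamma"), net.G("stem.bn.gamma"),
              net.G("stem.bn.beta"), rc.stembn);
  conv_bwd(da, net.P("stem.conv.W"), net.G("stem.conv.W"),
           net.G("stem.conv.b"), rc.stem);
}

// --------------------------------------------------------- net assembly

struct Model {
  std::string arch;
  Net net;
  MCfg mc;
  RCfg rc;
  bool isRes = false;

  void build(const std::string& a, const List& cfg) {
    arch = a;
    isRes = (a == "resnet18_1d");
    if (isRes) {
      rc = readRCfg(cfg);
      registerResnet(net, rc);
    } else {
      mc = readMCfg(cfg, a);
      registerMscnn(net, mc);
    }
  }
  int inputLength() const { return isRes ? rc.L : mc.L; }
  fmat forward(const fmat& X, int N, bool train, MCache& m, RCache& r) {
    return isRes ? resnet_fwd(net, rc, X, N, train, r)
                 : mscnn_fwd(net, mc, X, N, train, m);
  }
  void backward(const fmat& dY, MCache& m, RCache& r) {
    if (isRes) resnet_bwd(net, rc, dY, r);
    else mscnn_bwd(net, mc, dY, m);
  }
};

void importTensors(std::vector<Tensor>& ts, const List& src,
                   std::map<std::string, int>& idx) {
  for (auto& kv : idx) {
    if (!src.containsElementNamed(kv.first.c_str()))
      Rcpp::stop("missing parameter: " + kv.first);
    Rcpp::NumericVector v = src[kv.first];
    Tensor& t = ts[kv.second];
    if (static_cast<uword>(v.size()) != t.v.n_elem)
      Rcpp::stop("size mismatch for parameter: " + kv.first);
    for (uword i = 0; i < t.v.n_elem; ++i)
      t.v[i] = static_cast<float>(v[i]);
  }
}

List exportTensors(const std::vector<Tensor>& ts, bool grads = false) {
  List out(ts.size());
  Rcpp::CharacterVector nm(ts.size());
  for (size_t j = 0; j < ts.size(); ++j) {
    const Tensor& t = ts[j];
    const fmat& src = grads ? t.g : t.v;
    Rcpp::NumericVector v(src.n_elem);
    for (uword i = 0; i < src.n_elem; ++i) v[i] = src[i];
    if (!t.rdim.empty())
      v.attr("dim") = Rcpp::IntegerVector(t.rdim.begin(), t.rdim.end());
    else if (src.n_cols > 1)
      v.attr("dim") = Rcpp::IntegerVector::create(src.n_rows, src.n_cols);
    out[j] = v;
    nm[j] = t.name;
  }
  out.attr("names") = nm;
  return out;
}

// X: N x B R matrix -> (B x N) float, one sample per column
fmat toSamples(const Rcpp::NumericMatrix& X) {
  fmat out(X.ncol(), X.nrow());
  for (int n = 0; n < X.nrow(); ++n)
    for (int b = 0; b < X.ncol(); ++b)
      out(b, n) = static_cast<float>(X(n, b));
  return out;
}

// gather samples idx into a (1, B*n) activation row
fmat gatherBatch(const fmat& S, const std::vector<int>& idx, int from, int n) {
  const int B = S.n_rows;
  fmat out(1, static_cast<size_t>(B) * n);
  for (int j = 0; j < n; ++j)
    std::memcpy(out.memptr() + static_cast<size_t>(j) * B,
                S.colptr(idx[from + j]), sizeof(float) * B);
  return out;
}

void adamStep(Net& net, float lr, float b1, float b2, float eps) {
  net.step++;
  const float c1 = 1.0f - std::pow(b1, static_cast<float>(net.step));
  const float c2 = 1.0f - std::pow(b2, static_cast<float>(net.step));
  for (auto& t : net.ps) {
    t.m = b1 * t.m + (1.0f - b1) * t.g;
    t.w2 = b2 * t.w2 + (1.0f - b2) * square(t.g);
    t.v -= lr * (t.m / c1) / (sqrt(t.w2 / c2) + eps);
  }
}

double evalLoss(Model& mod, const fmat& S, const std::vector<int>& idx,
                const fvec& y) {
  // inference-mode MSE over the given samples, chunked
  const int chunk = 256;
  double sse = 0.0;
  MCache mc; RCache rc;
  for (size_t from = 0; from < idx.size(); from += chunk) {
    const int n = std::min<size_t>(chunk, idx.size() - from);
    fmat Xb = gatherBatch(S, idx, from, n);
    fmat pred = mod.forward(Xb, n, false, mc, rc);
    for (int j = 0; j < n; ++j) {
      const double d = pred(0, j) - y[idx[from + j]];
      sse += d * d;
    }
  }
  return sse / idx.size();
}

}  // namespace

// ------------------------------------------------------------ R interface

// [[Rcpp::export]]
List cpp_nn_init(std::string arch, List cfg, int seed) {
  Model mod;
  mod.build(arch, cfg);
  mod.net.init(static_cast<uint32_t>(seed));
  return List::create(Named("params") = exportTensors(mod.net.ps),
                      Named("state") = exportTensors(mod.net.st));
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_nn_forward(std::string arch, List cfg, List params,
                                   List state, Rcpp::NumericMatrix X,
                                   bool train) {
  Model mod;
  mod.build(arch, cfg);
  importTensors(mod.net.ps, params, mod.net.pi);
  importTensors(mod.net.st, state, mod.net.si);
  fmat S = toSamples(X);
  const int N = X.nrow();
  Rcpp::NumericVector out(N);
  MCache mc; RCache rc;
  if (train) {
    std::vector<int> idx(N);
    for (int i = 0; i < N; ++i) idx[i] = i;
    fmat pred = mod.forward(gatherBatch(S, idx, 0, N), N, true, mc, rc);
    for (int i = 0; i < N; ++i) out[i] = pred(0, i);
  } else {
    const int chunk = 256;
    std::vector<int> idx(N);
    for (int i = 0; i < N; ++i) idx[i] = i;
    for (int from = 0; from < N; from += chunk) {
      const int n = std::min(chunk, N - from);
      fmat pred = mod.forward(gatherBatch(S, idx, from, n), n, false, mc, rc);
      for (int j = 0; j < n; ++j) out[from + j] = pred(0, j);
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_nn_grad(std::string arch, List cfg, List params, List state,
                 Rcpp::NumericMatrix X, Rcpp::NumericVector y, bool train) {
  Model mod;
  mod.build(arch, cfg);
  importTensors(mod.net.ps, params, mod.net.pi);
  importTensors(mod.net.st, state, mod.net.si);
  fmat S = toSamples(X);
  const int N = X.nrow();
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  MCache mc; RCache rc;
  mod.net.zeroGrad();
  fmat pred = mod.forward(gatherBatch(S, idx, 0, N), N, train, mc, rc);
  fmat dY(1, N);
  double loss = 0.0;
  for (int i = 0; i < N; ++i) {
    const double d = pred(0, i) - y[i];
    loss += d * d;
    dY(0, i) = static_cast<float>(2.0 * d / N);
  }
  loss /= N;
  mod.backward(dY, mc, rc);
  Rcpp::NumericVector preds(N);
  for (int i = 0; i < N; ++i) preds[i] = pred(0, i);
  return List::create(Named("loss") = loss, Named("preds") = preds,
                      Named("grads") = exportTensors(mod.net.ps, true));
}

// [[Rcpp::export]]
List cpp_nn_train(std::string arch, List cfg, List params, List state,
                  Rcpp::NumericMatrix X, Rcpp::NumericVector yR, List opts) {
  Model mod;
  mod.build(arch, cfg);
  importTensors(mod.net.ps, params, mod.net.pi);
  importTensors(mod.net.st, state, mod.net.si);

  const int seed = Rcpp::as<int>(opts["seed"]);
  const int epochs = Rcpp::as<int>(opts["epochs"]);
  const int batchSize = Rcpp::as<int>(opts["batchSize"]);
  const float lr = static_cast<float>(Rcpp::as<double>(opts["lr"]));
  const bool earlyStopping = Rcpp::as<bool>(opts["earlyStopping"]);
  const int patience = Rcpp::as<int>(opts["patience"]);
  const double valFraction = Rcpp::as<double>(opts["valFraction"]);

  fmat S = toSamples(X);
  const int N = X.nrow();
  fvec y(N);
  for (int i = 0; i < N; ++i) y[i] = static_cast<float>(yR[i]);

  RNG rng(static_cast<uint32_t>(seed) * 2654435761u + 1u);
  std::vector<int> all(N);
  for (int i = 0; i < N; ++i) all[i] = i;

  std::vector<int> trainIdx = all, valIdx;
  if (earlyStopping) {
    std::vector<int> perm = all;
    rng.shuffle(perm);
    int nVal = std::max(1, static_cast<int>(std::floor(valFraction * N)));
    if (nVal >= N) nVal = N - 1;
    valIdx.assign(perm.begin(), perm.begin() + nVal);
    trainIdx.assign(perm.begin() + nVal, perm.end());
    std::sort(trainIdx.begin(), trainIdx.end());
    std::sort(valIdx.begin(), valIdx.end());
  }

  std::vector<double> trainLoss, valLoss;
  double bestVal = std::numeric_limits<double>::infinity();
  int bestEpoch = -1, wait = 0;
  std::vector<fmat> bestP, bestS;

  MCache mcc; RCache rcc;
  const int nTrain = static_cast<int>(trainIdx.size());
  for (int ep = 0; ep < epochs; ++ep) {
    std::vector<int> order = trainIdx;
    rng.shuffle(order);
    double sse = 0.0;
    for (int from = 0; from < nTrain; from += batchSize) {
      const int n = std::min(batchSize, nTrain - from);
      fmat Xb = gatherBatch(S, order, from, n);
      mod.net.zeroGrad();
      fmat pred = mod.forward(Xb, n, true, mcc, rcc);
      fmat dY(1, n);
      for (int j = 0; j < n; ++j) {
        const double d = pred(0, j) - y[order[from + j]];
        sse += d * d;
        dY(0, j) = static_cast<float>(2.0 * d / n);
      }
      mod.backward(dY, mcc, rcc);
      adamStep(mod.net, lr, 0.9f, 0.999f, 1e-8f);
    }
    trainLoss.push_back(sse / nTrain);
    if (!std::isfinite(trainLoss.back())) break;
    if (earlyStopping) {
      const double vl = evalLoss(mod, S, valIdx, y);
      valLoss.push_back(vl);
      if (vl < bestVal) {
        bestVal = vl;
        bestEpoch = ep;
        wait = 0;
        bestP.clear(); bestS.clear();
        for (auto& t : mod.net.ps) bestP.push_back(t.v);
        for (auto& t : mod.net.st) bestS.push_back(t.v);
      } else if (++wait > patience) {
        break;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  if (earlyStopping && bestEpoch >= 0) {
    for (size_t i = 0; i < mod.net.ps.size(); ++i) mod.net.ps[i].v = bestP[i];
    for (size_t i = 0; i < mod.net.st.size(); ++i) mod.net.st[i].v = bestS[i];
  }

  List hist = List::create(Named("train") = Rcpp::wrap(trainLoss),
                           Named("val") = Rcpp::wrap(valLoss),
                           Named("bestEpoch") = bestEpoch + 1);
  return List::create(Named("params") = exportTensors(mod.net.ps),
                      Named("state") = exportTensors(mod.net.st),
                      Named("history") = hist);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_nn_param_count(std::string arch, List cfg) {
  Model mod;
  mod.build(arch, cfg);
  double n = 0;
  for (auto& t : mod.net.ps) n += t.v.n_elem;
  return Rcpp::NumericVector::create(n);
}
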