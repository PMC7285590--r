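// Compact CPU implementations of the three reference architectures:
//   (1) embedding -> LSTM(12) -> sigmoid unit, MAE loss        (peptide affinity)
//   (2) embedding -> conv1d(36, k=9, stride 1) -> LSTM(12) ...  (CNN-LSTM variant)
//   (3) Siamese conv encoder (4 modules: conv/ReLU/batchnorm/avgpool,
//       global average pooling in module 4) -> MLP head, BCE    (PPI)
// Trained with Adam. All randomness goes through a private mt19937 so that
// identical (data, config, seed) give identical histories on one platform.
//
// Token matrices arrive 0-based; row i of the 21 x d embedding matrix is the
// vector of token i (0 = padding). Frozen embeddings are never written to.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Rng {
  std::mt19937 eng;
  explicit Rng(unsigned int seed) : eng(seed) {}
  double unif(double a, double b) {
    std::uniform_real_distribution<double> d(a, b);
    return d(eng);
  }
  mat umat(int r, int c, double a, double b) {
    mat m(r, c);
    for (uword j = 0; j < m.n_cols; ++j)
      for (uword i = 0; i < m.n_rows; ++i) m(i, j) = unif(a, b);
    return m;
  }
  mat glorot(int fan_in, int fan_out, int r, int c) {
    double lim = std::sqrt(6.0 / (fan_in + fan_out));
    return umat(r, c, -lim, lim);
  }
};

// ---------------------------------------------------------------- Adam ----

struct Adam {
  std::vector<mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8, lr;
  long t = 0;
  explicit Adam(double lr_) : lr(lr_) {}
  void ensure(size_t n, const std::vector<mat*>& params) {
    if (m.size() == n) return;
    m.resize(n); v.resize(n);
    for (size_t i = 0; i < n; ++i) {
      m[i] = zeros(params[i]->n_rows, params[i]->n_cols);
      v[i] = zeros(params[i]->n_rows, params[i]->n_cols);
    }
  }
  void step(std::vector<mat*> params, std::vector<mat*> grads) {
    ensure(params.size(), params);
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t), c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * (*grads[i]);
      v[i] = b2 * v[i] + (1 - b2) * square(*grads[i]);
      *params[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

// ------------------------------------------------------------ HLA models ----

struct HlaNet {
  mat E;                 // 21 x d
  mat Wc; rowvec bc;     // conv (optional): (k*d) x F
  mat Wx, Wh; rowvec b;  // LSTM input/recurrent weights, bias (4H, i|f|g|o)
  vec wo; double bo;     // output unit
  bool use_conv; int k, F, H, d;
};

static HlaNet hla_unpack(const List& w) {
  HlaNet n;
  n.E = Rcpp::as<mat>(w["E"]);
  n.use_conv = Rcpp::as<bool>(w["use_conv"]);
  n.k = Rcpp::as<int>(w["kernel"]); n.F = Rcpp::as<int>(w["filters"]);
  n.H = Rcpp::as<int>(w["units"]);  n.d = n.E.n_cols;
  if (n.use_conv) { n.Wc = Rcpp::as<mat>(w["Wc"]); n.bc = Rcpp::as<rowvec>(w["bc"]); }
  n.Wx = Rcpp::as<mat>(w["Wx"]); n.Wh = Rcpp::as<mat>(w["Wh"]);
  n.b = Rcpp::as<rowvec>(w["b"]);
  n.wo = Rcpp::as<vec>(w["wo"]); n.bo = Rcpp::as<double>(w["bo"]);
  return n;
}

static List hla_pack(const HlaNet& n) {
  List w = List::create(
    Named("E") = n.E, Named("use_conv") = n.use_conv, Named("kernel") = n.k,
    Named("filters") = n.F, Named("units") = n.H,
    Named("Wx") = n.Wx, Named("Wh") = n.Wh, Named("b") = n.b,
    Named("wo") = n.wo, Named("bo") = n.bo);
  if (n.use_conv) { w["Wc"] = n.Wc; w["bc"] = n.bc; }
  return w;
}

// [[Rcpp::export]]
List cpp_hla_init(const arma::mat& emb, bool use_conv, int filters, int kernel,
                  int units, int seed) {
  Rng rng((unsigned int)seed);
  HlaNet n;
  n.E = emb; n.use_conv = use_conv; n.k = kernel; n.F = filters; n.H = units;
  n.d = emb.n_cols;
  int din = use_conv ? filters : n.d;
  if (use_conv) {
    n.Wc = rng.glorot(kernel * n.d, filters, kernel * n.d, filters);
    n.bc = zeros<rowvec>(filters);
  }
  n.Wx = rng.glorot(din, 4 * units, din, 4 * units);
  n.Wh = rng.glorot(units, 4 * units, units, 4 * units);
  n.b = zeros<rowvec>(4 * units);
  n.b.subvec(units, 2 * units - 1).fill(1.0);  // forget-gate bias
  n.wo = rng.glorot(units, 1, units, 1).col(0);
  n.bo = 0.0;
  return hla_pack(n);
}

struct HlaGrads {
  mat dE, dWc, dWx, dWh; rowvec dbc, db; vec dwo; double dbo;
};

// Forward (and optional backward) pass over one batch.
// X: B x L 0-based tokens. If gr != nullptr, fill gradients of mean MAE.
static vec hla_forward(const HlaNet& n, const imat& X, const vec* y,
                       double* loss_out, HlaGrads* gr) {
  int B = X.n_rows, L = X.n_cols, H = n.H, d = n.d;
  int Tlen = n.use_conv ? (L - n.k + 1) : L;
  int din = n.use_conv ? n.F : d;

  mat M, A, C;  // conv im2col, pre-activation, activation
  if (n.use_conv) {
    M.set_size(B * Tlen, n.k * d);
    for (int i = 0; i < B; ++i)
      for (int t = 0; t < Tlen; ++t)
        for (int j = 0; j < n.k; ++j)
          M.row(i * Tlen + t).subvec(j * d, (j + 1) * d - 1) = n.E.row(X(i, t + j));
    A = M * n.Wc;
    A.each_row() += n.bc;
    C = clamp(A, 0.0, datum::inf);  // ReLU
  }

  // LSTM
  std::vector<mat> Xt(Tlen), gi(Tlen), gf(Tlen), gg(Tlen), go(Tlen),
      cs(Tlen), tc(Tlen), hs(Tlen);
  mat h = zeros(B, H), c = zeros(B, H);
  for (int t = 0; t < Tlen; ++t) {
    mat xt(B, din);
    if (n.use_conv) {
      for (int i = 0; i < B; ++i) xt.row(i) = C.row(i * Tlen + t);
    } else {
      for (int i = 0; i < B; ++i) xt.row(i) = n.E.row(X(i, t));
    }
    mat Z = xt * n.Wx + h * n.Wh;
    Z.each_row() += n.b;
    mat i_ = sigm(Z.cols(0, H - 1)), f_ = sigm(Z.cols(H, 2 * H - 1));
    mat g_ = tanh(Z.cols(2 * H, 3 * H - 1)), o_ = sigm(Z.cols(3 * H, 4 * H - 1));
    c = f_ % c + i_ % g_;
    mat tch = tanh(c);
    h = o_ % tch;
    Xt[t] = xt; gi[t] = i_; gf[t] = f_; gg[t] = g_; go[t] = o_;
    cs[t] = c; tc[t] = tch; hs[t] = h;
  }
  vec logit = h * n.wo + n.bo;
  vec pred = 1.0 / (1.0 + exp(-logit));

  if (y != nullptr && loss_out != nullptr)
    *loss_out = mean(abs(pred - *y));
  if (gr == nullptr) return pred;

  // ---- backward (mean absolute error) ----
  vec dpred = sign(pred - *y) / (double)B;
  vec dz = dpred % pred % (1.0 - pred);
  gr->dwo = hs[Tlen - 1].t() * dz;
  gr->dbo = accu(dz);
  mat dh = dz * n.wo.t();
  mat dc = zeros(B, H);
  gr->dWx = zeros(size(n.Wx)); gr->dWh = zeros(size(n.Wh));
  gr->db = zeros<rowvec>(4 * H);
  gr->dE = zeros(size(n.E));
  mat dC;
  if (n.use_conv) dC = zeros(B * Tlen, n.F);
  for (int t = Tlen - 1; t >= 0; --t) {
    mat do_ = dh % tc[t];
    dc += dh % go[t] % (1.0 - square(tc[t]));
    mat cprev = (t == 0) ? zeros(B, H) : cs[t - 1];
    mat di = dc % gg[t], dg = dc % gi[t], df = dc % cprev;
    mat dcprev = dc % gf[t];
    mat dZ(B, 4 * H);
    dZ.cols(0, H - 1) = di % gi[t] % (1.0 - gi[t]);
    dZ.cols(H, 2 * H - 1) = df % gf[t] % (1.0 - gf[t]);
    dZ.cols(2 * H, 3 * H - 1) = dg % (1.0 - square(gg[t]));
    dZ.cols(3 * H, 4 * H - 1) = do_ % go[t] % (1.0 - go[t]);
    gr->dWx += Xt[t].t() * dZ;
    mat hprev = (t == 0) ? zeros(B, H) : hs[t - 1];
    gr->dWh += hprev.t() * dZ;
    gr->db += sum(dZ, 0);
    mat dxt = dZ * n.Wx.t();
    dh = dZ * n.Wh.t();
    dc = dcprev;
    if (n.use_conv) {
      for (int i = 0; i < B; ++i) dC.row(i * Tlen + t) = dxt.row(i);
    } else {
      for (int i = 0; i < B; ++i) gr->dE.row(X(i, t)) += dxt.row(i);
    }
  }
  if (n.use_conv) {
    mat dA = dC % conv_to<mat>::from(A > 0.0);
    gr->dWc = M.t() * dA;
    gr->dbc = sum(dA, 0);
    mat dM = dA * n.Wc.t();
    for (int i = 0; i < B; ++i)
      for (int t = 0; t < Tlen; ++t)
        for (int j = 0; j < n.k; ++j)
          gr->dE.row(X(i, t + j)) +=
            dM.row(i * Tlen + t).subvec(j * d, (j + 1) * d - 1);
  }
  return pred;
}

// [[Rcpp::export]]
arma::vec cpp_hla_predict(const List& weights, const arma::imat& X) {
  HlaNet n = hla_unpack(weights);
  return hla_forward(n, X, nullptr, nullptr, nullptr);
}

// [[Rcpp::export]]
double cpp_hla_loss(const List& weights, const arma::imat& X, const arma::vec& y) {
  HlaNet n = hla_unpack(weights);
  double loss = 0;
  hla_forward(n, X, &y, &loss, nullptr);
  return loss;
}

// [[Rcpp::export]]
List cpp_hla_grad(const List& weights, const arma::imat& X, const arma::vec& y) {
  HlaNet n = hla_unpack(weights);
  HlaGrads g; double loss = 0;
  hla_forward(n, X, &y, &loss, &g);
  List out = List::create(
    Named("dE") = g.dE, Named("dWx") = g.dWx, Named("dWh") = g.dWh,
    Named("db") = g.db, Named("dwo") = g.dwo, Named("dbo") = g.dbo,
    Named("loss") = loss);
  if (n.use_conv) { out["dWc"] = g.dWc; out["dbc"] = g.dbc; }
  return out;
}

// [[Rcpp::export]]
List cpp_hla_train(const List& weights, const arma::imat& Xtr, const arma::vec& ytr,
                   const arma::imat& Xval, const arma::vec& yval, int epochs,
                   int batch, double lr, bool train_emb, int seed) {
  HlaNet n = hla_unpack(weights);
  Rng rng((unsigned int)seed);
  Adam opt(lr);
  int N = Xtr.n_rows;
  vec tr_loss(epochs), va_loss(epochs);
  mat va_pred(epochs, Xval.n_rows);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng.eng);
    double ep_loss = 0; int nb = 0;
    for (int s = 0; s < N; s += batch) {
      int e = std::min(N, s + batch), B = e - s;
      imat Xb(B, Xtr.n_cols); vec yb(B);
      for (int i = 0; i < B; ++i) { Xb.row(i) = Xtr.row(idx[s + i]); yb(i) = ytr(idx[s + i]); }
      HlaGrads g; double loss = 0;
      hla_forward(n, Xb, &yb, &loss, &g);
      ep_loss += loss; ++nb;
      std::vector<mat*> P, G;
      mat dbm = conv_to<mat>::from(g.db), bm = conv_to<mat>::from(n.b);
      // Adam over matrices; row vectors / scalars handled as 1x* mats
      mat dbo(1, 1); dbo(0, 0) = g.dbo; mat bo(1, 1); bo(0, 0) = n.bo;
      mat dwo = conv_to<mat>::from(g.dwo), wo = conv_to<mat>::from(n.wo);
      if (train_emb) { P.push_back(&n.E); G.push_back(&g.dE); }
      if (n.use_conv) { P.push_back(&n.Wc); G.push_back(&g.dWc); }
      P.push_back(&n.Wx); G.push_back(&g.dWx);
      P.push_back(&n.Wh); G.push_back(&g.dWh);
      // pack rowvec/vec/scalar params into temporary mats, step, write back
      mat bcm, dbcm;
      if (n.use_conv) { bcm = conv_to<mat>::from(n.bc); dbcm = conv_to<mat>::from(g.dbc); P.push_back(&bcm); G.push_back(&dbcm); }
      P.push_back(&bm); G.push_back(&dbm);
      P.push_back(&wo); G.push_back(&dwo);
      P.push_back(&bo); G.push_back(&dbo);
      opt.step(P, G);
      n.b = conv_to<rowvec>::from(bm);
      n.wo = wo.col(0); n.bo = bo(0, 0);
      if (n.use_conv) n.bc = conv_to<rowvec>::from(bcm);
    }
    tr_loss(ep) = ep_loss / nb;
    double vloss = 0;
    vec vp = hla_forward(n, Xval, &yval, &vloss, nullptr);
    va_loss(ep) = vloss;
    va_pred.row(ep) = vp.t();
  }
  return List::create(Named("weights") = hla_pack(n), Named("train_loss") = tr_loss,
                      Named("val_loss") = va_loss, Named("val_pred") = va_pred);
}

// --------------------------------------------------------- Siamese model ----

struct BnLayer { rowvec gamma, beta, rmean, rvar; };

struct SiamNet {
  mat E;
  std::vector<mat> Wc;      // (k_m * C_in) x F_m
  std::vector<rowvec> bc;
  std::vector<BnLayer> bn;
  ivec filters, kernels;
  int pool, hidden, d;
  bool symmetric;
  mat W1; rowvec b1; vec w2; double b2;
};

static SiamNet siam_unpack(const List& w) {
  SiamNet n;
  n.E = Rcpp::as<mat>(w["E"]); n.d = n.E.n_cols;
  n.filters = Rcpp::as<ivec>(w["filters"]); n.kernels = Rcpp::as<ivec>(w["kernels"]);
  n.pool = Rcpp::as<int>(w["pool"]); n.hidden = Rcpp::as<int>(w["hidden"]);
  n.symmetric = Rcpp::as<bool>(w["symmetric"]);
  List Wc = w["Wc"], bc = w["bc"], gam = w["bn_gamma"], bet = w["bn_beta"],
       rm = w["bn_rmean"], rv = w["bn_rvar"];
  for (int m = 0; m < 4; ++m) {
    n.Wc.push_back(Rcpp::as<mat>(Wc[m]));
    n.bc.push_back(Rcpp::as<rowvec>(bc[m]));
    BnLayer L;
    L.gamma = Rcpp::as<rowvec>(gam[m]); L.beta = Rcpp::as<rowvec>(bet[m]);
    L.rmean = Rcpp::as<rowvec>(rm[m]); L.rvar = Rcpp::as<rowvec>(rv[m]);
    n.bn.push_back(L);
  }
  n.W1 = Rcpp::as<mat>(w["W1"]); n.b1 = Rcpp::as<rowvec>(w["b1"]);
  n.w2 = Rcpp::as<vec>(w["w2"]); n.b2 = Rcpp::as<double>(w["b2"]);
  return n;
}

static List siam_pack(const SiamNet& n) {
  List Wc(4), bc(4), gam(4), bet(4), rm(4), rv(4);
  for (int m = 0; m < 4; ++m) {
    Wc[m] = n.Wc[m]; bc[m] = n.bc[m];
    gam[m] = n.bn[m].gamma; bet[m] = n.bn[m].beta;
    rm[m] = n.bn[m].rmean; rv[m] = n.bn[m].rvar;
  }
  return List::create(
    Named("E") = n.E, Named("filters") = n.filters, Named("kernels") = n.kernels,
    Named("pool") = n.pool, Named("hidden") = n.hidden,
    Named("symmetric") = n.symmetric,
    Named("Wc") = Wc, Named("bc") = bc, Named("bn_gamma") = gam,
    Named("bn_beta") = bet, Named("bn_rmean") = rm, Named("bn_rvar") = rv,
    Named("W1") = n.W1, Named("b1") = n.b1, Named("w2") = n.w2,
    Named("b2") = n.b2);
}

// [[Rcpp::export]]
List cpp_siamese_init(const arma::mat& emb, const arma::ivec& filters,
                      const arma::ivec& kernels, int pool, int hidden,
                      bool symmetric, int seed) {
  Rng rng((unsigned int)seed);
  SiamNet n;
  n.E = emb; n.d = emb.n_cols; n.filters = filters; n.kernels = kernels;
  n.pool = pool; n.hidden = hidden; n.symmetric = symmetric;
  int cin = n.d;
  for (int m = 0; m < 4; ++m) {
    int k = kernels(m), F = filters(m);
    n.Wc.push_back(rng.glorot(k * cin, F, k * cin, F));
    n.bc.push_back(zeros<rowvec>(F));
    BnLayer L;
    L.gamma = ones<rowvec>(F); L.beta = zeros<rowvec>(F);
    L.rmean = zeros<rowvec>(F); L.rvar = ones<rowvec>(F);
    n.bn.push_back(L);
    cin = F;
  }
  int fdim = 2 * filters(3);
  n.W1 = rng.glorot(fdim, hidden, fdim, hidden);
  n.b1 = zeros<rowvec>(hidden);
  n.w2 = rng.glorot(hidden, 1, hidden, 1).col(0);
  n.b2 = 0.0;
  return siam_pack(n);
}

static const double BN_EPS = 1e-5, BN_MOM = 0.9;

struct ModCache {
  mat M, A, xhat, pooled;  // im2col, conv pre-act, bn normalized, pool output
  rowvec mu, var;
  int Lin, Lout, Lp;
};

// Shared encoder forward over stacked batch. R_in layout: (N*L) x C, sample-major.
// Returns per-sample vectors (N x F4). If caches != nullptr store for backward.
static mat siam_encode(SiamNet& n, const imat& X, bool training,
                       std::vector<ModCache>* caches) {
  int N = X.n_rows, L = X.n_cols;
  mat R(N * L, n.d);
  for (int i = 0; i < N; ++i)
    for (int t = 0; t < L; ++t) R.row(i * L + t) = n.E.row(X(i, t));
  int Lin = L;
  mat out;
  for (int m = 0; m < 4; ++m) {
    int k = n.kernels(m), F = n.filters(m), cin = n.Wc[m].n_rows / k;
    int Lout = Lin - k + 1;
    if (Lout < 1) Rcpp::stop("sequence too short for convolution stack");
    mat M(N * Lout, k * cin);
    for (int i = 0; i < N; ++i)
      for (int t = 0; t < Lout; ++t)
        for (int j = 0; j < k; ++j)
          M.row(i * Lout + t).subvec(j * cin, (j + 1) * cin - 1) =
            R.row(i * Lin + t + j);
    mat A = M * n.Wc[m];
    A.each_row() += n.bc[m];
    mat C = clamp(A, 0.0, datum::inf);
    rowvec mu, var;
    mat xhat;
    if (training) {
      mu = mean(C, 0);
      var = mean(square(C.each_row() - mu), 0);
      xhat = (C.each_row() - mu).each_row() / sqrt(var + BN_EPS);
      n.bn[m].rmean = BN_MOM * n.bn[m].rmean + (1 - BN_MOM) * mu;
      n.bn[m].rvar = BN_MOM * n.bn[m].rvar + (1 - BN_MOM) * var;
    } else {
      xhat = (C.each_row() - n.bn[m].rmean).each_row() / sqrt(n.bn[m].rvar + BN_EPS);
    }
    mat Bn = (xhat.each_row() % n.bn[m].gamma).each_row() + n.bn[m].beta;
    mat P;
    int Lp;
    if (m < 3) {
      Lp = Lout / n.pool;
      if (Lp < 1) Rcpp::stop("sequence too short for pooling stack");
      P.set_size(N * Lp, F);
      for (int i = 0; i < N; ++i)
        for (int q = 0; q < Lp; ++q) {
          rowvec acc = zeros<rowvec>(F);
          for (int j = 0; j < n.pool; ++j) acc += Bn.row(i * Lout + q * n.pool + j);
          P.row(i * Lp + q) = acc / n.pool;
        }
    } else {  // global average pooling
      Lp = 1;
      P.set_size(N, F);
      for (int i = 0; i < N; ++i) {
        rowvec acc = zeros<rowvec>(F);
        for (int t = 0; t < Lout; ++t) acc += Bn.row(i * Lout + t);
        P.row(i) = acc / Lout;
      }
    }
    if (caches != nullptr) {
      ModCache cc; cc.M = M; cc.A = A; cc.xhat = xhat; cc.pooled = P;
      cc.mu = mu; cc.var = var; cc.Lin = Lin; cc.Lout = Lout; cc.Lp = Lp;
      caches->push_back(cc);
    }
    R = P; Lin = Lp;
  }
  out = R;  // N x F4
  return out;
}

struct SiamGrads {
  mat dE; std::vector<mat> dWc; std::vector<rowvec> dbc, dgamma, dbeta;
  mat dW1; rowvec db1; vec dw2; double db2;
};

static vec siam_forward(SiamNet& n, const imat& Xa, const imat& Xb, const vec* y,
                        bool training, double* loss_out, SiamGrads* gr) {
  int B = Xa.n_rows, L = Xa.n_cols;
  imat X(2 * B, L);
  X.rows(0, B - 1) = Xa; X.rows(B, 2 * B - 1) = Xb;
  std::vector<ModCache> caches;
  mat Z = siam_encode(n, X, training, gr ? &caches : nullptr);
  mat u = Z.rows(0, B - 1), v = Z.rows(B, 2 * B - 1);
  int F4 = n.filters(3);
  mat feat(B, 2 * F4);
  if (n.symmetric) {
    feat.cols(0, F4 - 1) = u % v;
    feat.cols(F4, 2 * F4 - 1) = abs(u - v);
  } else {
    feat.cols(0, F4 - 1) = u;
    feat.cols(F4, 2 * F4 - 1) = v;
  }
  mat Z1 = feat * n.W1;
  Z1.each_row() += n.b1;
  mat A1 = clamp(Z1, 0.0, datum::inf);
  vec logit = A1 * n.w2 + n.b2;
  vec p = 1.0 / (1.0 + exp(-logit));
  if (y != nullptr && loss_out != nullptr) {
    vec pc = clamp(p, 1e-12, 1.0 - 1e-12);
    *loss_out = -mean((*y) % log(pc) + (1.0 - *y) % log(1.0 - pc));
  }
  if (gr == nullptr) return p;

  // backward, BCE through sigmoid
  vec dlogit = (p - *y) / (double)B;
  gr->dw2 = A1.t() * dlogit;
  gr->db2 = accu(dlogit);
  mat dA1 = dlogit * n.w2.t();
  mat dZ1 = dA1 % conv_to<mat>::from(Z1 > 0.0);
  gr->dW1 = feat.t() * dZ1;
  gr->db1 = sum(dZ1, 0);
  mat dfeat = dZ1 * n.W1.t();
  mat du(B, F4), dv(B, F4);
  if (n.symmetric) {
    mat d1 = dfeat.cols(0, F4 - 1), d2 = dfeat.cols(F4, 2 * F4 - 1);
    mat s = sign(u - v);
    du = d1 % v + d2 % s;
    dv = d1 % u - d2 % s;
  } else {
    du = dfeat.cols(0, F4 - 1);
    dv = dfeat.cols(F4, 2 * F4 - 1);
  }
  mat dZall(2 * B, F4);
  dZall.rows(0, B - 1) = du; dZall.rows(B, 2 * B - 1) = dv;

  // back through the four modules
  gr->dWc.assign(4, mat()); gr->dbc.assign(4, rowvec());
  gr->dgamma.assign(4, rowvec()); gr->dbeta.assign(4, rowvec());
  gr->dE = zeros(size(n.E));
  int N = 2 * B;
  mat dP = dZall;  // gradient wrt pooled output of current (last) module
  for (int m = 3; m >= 0; --m) {
    ModCache& cc = caches[m];
    int F = n.filters(m), k = n.kernels(m), cin = n.Wc[m].n_rows / k;
    // unpool
    mat dBn(N * cc.Lout, F, fill::zeros);
    if (m < 3) {
      for (int i = 0; i < N; ++i)
        for (int q = 0; q < cc.Lp; ++q)
          for (int j = 0; j < n.pool; ++j)
            dBn.row(i * cc.Lout + q * n.pool + j) =
              dP.row(i * cc.Lp + q) / n.pool;
    } else {
      for (int i = 0; i < N; ++i)
        for (int t = 0; t < cc.Lout; ++t)
          dBn.row(i * cc.Lout + t) = dP.row(i) / cc.Lout;
    }
    // batchnorm backward (training statistics)
    gr->dgamma[m] = sum(dBn % cc.xhat, 0);
    gr->dbeta[m] = sum(dBn, 0);
    mat dxhat = dBn.each_row() % n.bn[m].gamma;
    rowvec invstd = 1.0 / sqrt(cc.var + BN_EPS);
    rowvec m1 = mean(dxhat, 0), m2 = mean(dxhat % cc.xhat, 0);
    mat dC = dxhat;
    dC.each_row() -= m1;
    mat xm = cc.xhat;
    xm.each_row() %= m2;
    dC -= xm;
    dC.each_row() %= invstd;
    // relu + conv
    mat dA = dC % conv_to<mat>::from(cc.A > 0.0);
    gr->dWc[m] = cc.M.t() * dA;
    gr->dbc[m] = sum(dA, 0);
    mat dM = dA * n.Wc[m].t();
    if (m > 0) {
      mat dRin(N * cc.Lin, cin, fill::zeros);
      for (int i = 0; i < N; ++i)
        for (int t = 0; t < cc.Lout; ++t)
          for (int j = 0; j < k; ++j)
            dRin.row(i * cc.Lin + t + j) +=
              dM.row(i * cc.Lout + t).subvec(j * cin, (j + 1) * cin - 1);
      dP = dRin;
    } else {
      for (int i = 0; i < N; ++i)
        for (int t = 0; t < cc.Lout; ++t)
          for (int j = 0; j < k; ++j)
            gr->dE.row(X(i, t + j)) +=
              dM.row(i * cc.Lout + t).subvec(j * cin, (j + 1) * cin - 1);
    }
  }
  return p;
}

// [[Rcpp::export]]
arma::vec cpp_siamese_predict(const List& weights, const arma::imat& Xa,
                              const arma::imat& Xb, bool training = false) {
  SiamNet n = siam_unpack(weights);
  return siam_forward(n, Xa, Xb, nullptr, training, nullptr, nullptr);
}

// [[Rcpp::export]]
arma::mat cpp_siamese_encode(const List& weights, const arma::imat& X,
                             bool training = false) {
  SiamNet n = siam_unpack(weights);
  return siam_encode(n, X, training, nullptr);
}

// [[Rcpp::export]]
double cpp_siamese_loss(const List& weights, const arma::imat& Xa,
                        const arma::imat& Xb, const arma::vec& y, bool training) {
  SiamNet n = siam_unpack(weights);
  double loss = 0;
  siam_forward(n, Xa, Xb, &y, training, &loss, nullptr);
  return loss;
}

// [[Rcpp::export]]
List cpp_siamese_grad(const List& weights, const arma::imat& Xa,
                      const arma::imat& Xb, const arma::vec& y) {
  SiamNet n = siam_unpack(weights);
  SiamGrads g; double loss = 0;
  siam_forward(n, Xa, Xb, &y, true, &loss, &g);
  List dWc(4), dbc(4), dgam(4), dbet(4);
  for (int m = 0; m < 4; ++m) {
    dWc[m] = g.dWc[m]; dbc[m] = g.dbc[m]; dgam[m] = g.dgamma[m]; dbet[m] = g.dbeta[m];
  }
  return List::create(Named("dE") = g.dE, Named("dWc") = dWc, Named("dbc") = dbc,
                      Named("dgamma") = dgam, Named("dbeta") = dbet,
                      Named("dW1") = g.dW1, Named("db1") = g.db1,
                      Named("dw2") = g.dw2, Named("db2") = g.db2,
                      Named("loss") = loss);
}

// [[Rcpp::export]]
List cpp_siamese_train(const List& weights, const arma::imat& Xa,
                       const arma::imat& Xb, const arma::vec& y,
                       const arma::imat& Xva, const arma::imat& Xvb,
                       const arma::vec& yv, int epochs, int batch, double lr,
                       bool train_emb, int seed) {
  SiamNet n = siam_unpack(weights);
  Rng rng((unsigned int)seed);
  Adam opt(lr);
  int N = Xa.n_rows;
  vec tr_loss(epochs), va_loss(epochs);
  mat va_pred(epochs, Xva.n_rows);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng.eng);
    double ep_loss = 0; int nb = 0;
    for (int s = 0; s < N; s += batch) {
      int e = std::min(N, s + batch), B = e - s;
      if (B < 2) continue;  // batch statistics need >= 2 stacked samples
      imat Xab(B, Xa.n_cols), Xbb(B, Xb.n_cols); vec yb(B);
      for (int i = 0; i < B; ++i) {
        Xab.row(i) = Xa.row(idx[s + i]); Xbb.row(i) = Xb.row(idx[s + i]);
        yb(i) = y(idx[s + i]);
      }
      SiamGrads g; double loss = 0;
      siam_forward(n, Xab, Xbb, &yb, true, &loss, &g);
      ep_loss += loss; ++nb;
      std::vector<mat*> P, G;
      if (train_emb) { P.push_back(&n.E); G.push_back(&g.dE); }
      std::vector<mat> tmpP, tmpG;
      tmpP.reserve(32); tmpG.reserve(32);
      for (int m = 0; m < 4; ++m) {
        P.push_back(&n.Wc[m]); G.push_back(&g.dWc[m]);
        tmpP.push_back(conv_to<mat>::from(n.bc[m]));
        tmpG.push_back(conv_to<mat>::from(g.dbc[m]));
        tmpP.push_back(conv_to<mat>::from(n.bn[m].gamma));
        tmpG.push_back(conv_to<mat>::from(g.dgamma[m]));
        tmpP.push_back(conv_to<mat>::from(n.bn[m].beta));
        tmpG.push_back(conv_to<mat>::from(g.dbeta[m]));
      }
      tmpP.push_back(conv_to<mat>::from(n.b1)); tmpG.push_back(conv_to<mat>::from(g.db1));
      tmpP.push_back(conv_to<mat>::from(n.w2)); tmpG.push_back(conv_to<mat>::from(g.dw2));
      mat b2m(1, 1); b2m(0, 0) = n.b2; mat db2m(1, 1); db2m(0, 0) = g.db2;
      tmpP.push_back(b2m); tmpG.push_back(db2m);
      P.push_back(&n.W1); G.push_back(&g.dW1);
      for (size_t i = 0; i < tmpP.size(); ++i) { P.push_back(&tmpP[i]); G.push_back(&tmpG[i]); }
      opt.step(P, G);
      // write packed params back
      size_t ti = 0;
      for (int m = 0; m < 4; ++m) {
        n.bc[m] = conv_to<rowvec>::from(tmpP[ti++]);
        n.bn[m].gamma = conv_to<rowvec>::from(tmpP[ti++]);
        n.bn[m].beta = conv_to<rowvec>::from(tmpP[ti++]);
      }
      n.b1 = conv_to<rowvec>::from(tmpP[ti++]);
      n.w2 = tmpP[ti++].col(0);
      n.b2 = tmpP[ti++](0, 0);
    }
    tr_loss(ep) = nb > 0 ? ep_loss / nb : datum::nan;
    double vloss = 0;
    vec vp = siam_forward(n, Xva, Xvb, &yv, false, &vloss, nullptr);
    va_loss(ep) = vloss;
    va_pred.row(ep) = vp.t();
  }
  return List::create(Named("weights") = siam_pack(n), Named("train_loss") = tr_loss,
                      Named("val_loss") = va_loss, Named("val_pred") = va_pred);
}
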