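// Two-layer LSTM binary classifier: seeded float32 training engine.
//
// Architecture (fixed): LSTM(h1, tanh cell, sigmoid gates, L2 on the input
// kernel) -> dropout -> LSTM(h2, same configuration) -> dropout ->
// dense(d, ReLU) -> dropout -> 2-unit softmax. Sparse categorical
// cross-entropy loss, Adam optimizer, mini-batch training with per-epoch
// shuffling, early stopping on validation accuracy with best-epoch weight
// restoration (earliest epoch wins ties). Single-threaded and fully
// deterministic given the seed: initialization, shuffling and dropout all
// draw from one Mersenne Twister stream.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int N_PAR = 10; // W1,U1,b1,W2,U2,b2,W3,b3,W4,b4

struct Net {
  std::vector<fmat> par;
  int k, h1, h2, d;
};

static fmat glorot(int nin, int nout, std::mt19937& rng) {
  float lim = std::sqrt(6.0f / (float)(nin + nout));
  std::uniform_real_distribution<float> u(-lim, lim);
  fmat m(nin, nout);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) m(i, j) = u(rng);
  return m;
}

static Net init_net(int k, int h1, int h2, int d, int seed) {
  std::mt19937 rng((unsigned)seed);
  Net net; net.k = k; net.h1 = h1; net.h2 = h2; net.d = d;
  net.par.resize(N_PAR);
  net.par[0] = glorot(k, 4 * h1, rng);        // W1
  net.par[1] = glorot(h1, 4 * h1, rng);       // U1
  net.par[2] = fmat(1, 4 * h1, fill::zeros);  // b1
  net.par[2].cols(h1, 2 * h1 - 1).fill(1.0f); // forget-gate bias 1
  net.par[3] = glorot(h1, 4 * h2, rng);       // W2
  net.par[4] = glorot(h2, 4 * h2, rng);       // U2
  net.par[5] = fmat(1, 4 * h2, fill::zeros);  // b2
  net.par[5].cols(h2, 2 * h2 - 1).fill(1.0f);
  net.par[6] = glorot(h2, d, rng);            // W3
  net.par[7] = fmat(1, d, fill::zeros);       // b3
  net.par[8] = glorot(d, 2, rng);             // W4
  net.par[9] = fmat(1, 2, fill::zeros);       // b4
  return net;
}

static Rcpp::List net_to_list(const Net& net) {
  const char* nm[N_PAR] = {"W1","U1","b1","W2","U2","b2","W3","b3","W4","b4"};
  Rcpp::List out;
  for (int i = 0; i < N_PAR; ++i)
    out[nm[i]] = Rcpp::wrap(conv_to<mat>::from(net.par[i]));
  out["dims"] = Rcpp::IntegerVector::create(net.k, net.h1, net.h2, net.d);
  return out;
}

static Net list_to_net(const Rcpp::List& lst) {
  const char* nm[N_PAR] = {"W1","U1","b1","W2","U2","b2","W3","b3","W4","b4"};
  Net net;
  net.par.resize(N_PAR);
  for (int i = 0; i < N_PAR; ++i)
    net.par[i] = conv_to<fmat>::from(Rcpp::as<mat>(lst[nm[i]]));
  Rcpp::IntegerVector d = lst["dims"];
  net.k = d[0]; net.h1 = d[1]; net.h2 = d[2]; net.d = d[3];
  return net;
}

static inline fmat sigm(const fmat& x) { return 1.0f / (1.0f + exp(-x)); }

struct LstmCache { fcube I, F, G, O, C, Tc, H; };

// X: (B, in, T); caches sized (B, h, T)
static void lstm_forward(const fcube& X, const fmat& W, const fmat& U,
                         const fmat& b, LstmCache& cc) {
  const uword B = X.n_rows, T = X.n_slices, h = U.n_rows;
  cc.I.set_size(B, h, T); cc.F.set_size(B, h, T); cc.G.set_size(B, h, T);
  cc.O.set_size(B, h, T); cc.C.set_size(B, h, T); cc.Tc.set_size(B, h, T);
  cc.H.set_size(B, h, T);
  fmat hprev(B, h, fill::zeros), cprev(B, h, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    fmat A = X.slice(t) * W + hprev * U;
    A.each_row() += b;
    fmat I = sigm(A.cols(0, h - 1));
    fmat F = sigm(A.cols(h, 2 * h - 1));
    fmat G = tanh(A.cols(2 * h, 3 * h - 1));
    fmat O = sigm(A.cols(3 * h, 4 * h - 1));
    fmat C = F % cprev + I % G;
    fmat Tc = tanh(C);
    fmat H = O % Tc;
    cc.I.slice(t) = I; cc.F.slice(t) = F; cc.G.slice(t) = G;
    cc.O.slice(t) = O; cc.C.slice(t) = C; cc.Tc.slice(t) = Tc;
    cc.H.slice(t) = H;
    hprev = H; cprev = C;
  }
}

// BPTT; dHin: gradient wrt the layer's (pre-dropout) output at each t.
// Returns gradient wrt the layer input in dX.
static void lstm_backward(const fcube& X, const LstmCache& cc,
                          const fmat& W, const fmat& U,
                          const fcube& dHin,
                          fmat& gW, fmat& gU, fmat& gb, fcube& dX) {
  const uword B = X.n_rows, T = X.n_slices, h = U.n_rows;
  gW.zeros(W.n_rows, W.n_cols); gU.zeros(U.n_rows, U.n_cols);
  gb.zeros(1, 4 * h);
  dX.set_size(B, X.n_cols, T);
  fmat dh(B, h, fill::zeros), dc(B, h, fill::zeros);
  fmat zerosBh(B, h, fill::zeros);
  for (int t = (int)T - 1; t >= 0; --t) {
    dh += dHin.slice(t);
    const fmat& I = cc.I.slice(t); const fmat& F = cc.F.slice(t);
    const fmat& G = cc.G.slice(t); const fmat& O = cc.O.slice(t);
    const fmat& Tc = cc.Tc.slice(t);
    dc += dh % O % (1.0f - square(Tc));
    fmat da_o = (dh % Tc) % O % (1.0f - O);
    fmat da_i = (dc % G) % I % (1.0f - I);
    fmat da_g = (dc % I) % (1.0f - square(G));
    const fmat& cprev = (t == 0) ? zerosBh : cc.C.slice(t - 1);
    fmat da_f = (dc % cprev) % F % (1.0f - F);
    fmat da = join_rows(da_i, da_f, da_g, da_o);
    gW += X.slice(t).t() * da;
    const fmat& hprev = (t == 0) ? zerosBh : cc.H.slice(t - 1);
    gU += hprev.t() * da;
    gb += sum(da, 0);
    dX.slice(t) = da * W.t();
    dh = da * U.t();
    dc = dc % F;
  }
}

static fmat softmax_rows(fmat z) {
  z.each_col() -= max(z, 1);
  fmat e = exp(z);
  e.each_col() /= sum(e, 1);
  return e;
}

// forward pass without dropout; X: (n examples) cube (T, k, n)
static fmat eval_forward(const Net& net, const cube& X) {
  const uword n = X.n_slices, T = X.n_rows, k = X.n_cols;
  fmat P(n, 2);
  const uword chunk = 1024;
  for (uword start = 0; start < n; start += chunk) {
    uword stop = std::min(n, start + chunk);
    uword B = stop - start;
    fcube Xb(B, k, T);
    for (uword t = 0; t < T; ++t)
      for (uword j = 0; j < k; ++j)
        for (uword b = 0; b < B; ++b)
          Xb(b, j, t) = (float)X(t, j, start + b);
    LstmCache c1, c2;
    lstm_forward(Xb, net.par[0], net.par[1], net.par[2], c1);
    lstm_forward(c1.H, net.par[3], net.par[4], net.par[5], c2);
    fmat A3 = c2.H.slice(T - 1) * net.par[6];
    A3.each_row() += net.par[7];
    fmat Z3 = clamp(A3, 0.0f, std::numeric_limits<float>::max());
    fmat logits = Z3 * net.par[8];
    logits.each_row() += net.par[9];
    P.rows(start, stop - 1) = softmax_rows(logits);
  }
  return P;
}

static double val_accuracy(const fmat& P, const ivec& y) {
  uvec pred = conv_to<uvec>::from(P.col(1) > P.col(0));
  double acc = 0;
  for (uword i = 0; i < y.n_elem; ++i) acc += (pred(i) == (uword)y(i));
  return acc / (double)y.n_elem;
}

static void dropout_mask(fmat& M, double rate, std::mt19937& rng) {
  if (rate <= 0) { M.ones(); return; }
  std::uniform_real_distribution<float> u(0.0f, 1.0f);
  float scale = 1.0f / (1.0f - (float)rate);
  for (uword j = 0; j < M.n_cols; ++j)
    for (uword i = 0; i < M.n_rows; ++i)
      M(i, j) = (u(rng) < rate) ? 0.0f : scale;
}

// [[Rcpp::export]]
Rcpp::List lstm_init_cpp(int k, int h1, int h2, int d, int seed) {
  return net_to_list(init_net(k, h1, h2, d, seed));
}

// [[Rcpp::export]]
arma::mat lstm_predict_cpp(Rcpp::List params, arma::cube X) {
  Net net = list_to_net(params);
  if ((int)X.n_cols != net.k)
    Rcpp::stop("input width %d does not match model width %d",
               (int)X.n_cols, net.k);
  return conv_to<mat>::from(eval_forward(net, X));
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(arma::cube Xtr, arma::ivec ytr,
                          arma::cube Xval, arma::ivec yval,
                          Rcpp::List init,
                          double lr, double l2,
                          double drop1, double drop2, double drop3,
                          int batch, int max_epochs, int patience, int seed) {
  Net net = list_to_net(init);
  const uword n = Xtr.n_slices, T = Xtr.n_rows, k = Xtr.n_cols;
  const int h1 = net.h1, h2 = net.h2, d = net.d;
  if ((int)k != net.k) Rcpp::stop("training input width mismatch");
  std::mt19937 rng((unsigned)seed + 0x9e3779b9u); // decouple from init stream

  // Adam state
  std::vector<fmat> m(N_PAR), v(N_PAR), g(N_PAR);
  for (int i = 0; i < N_PAR; ++i) {
    m[i] = fmat(size(net.par[i]), fill::zeros);
    v[i] = fmat(size(net.par[i]), fill::zeros);
  }
  const float b1a = 0.9f, b2a = 0.999f, eps = 1e-7f;
  long step = 0;

  std::vector<uword> order(n);
  for (uword i = 0; i < n; ++i) order[i] = i;

  mat history(max_epochs, 4);
  int best_epoch = 0;
  double best_val = -1.0;
  std::vector<fmat> best_par = net.par;
  int epochs_run = 0;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0, ep_correct = 0;
    for (uword start = 0; start < n; start += (uword)batch) {
      uword stop = std::min(n, start + (uword)batch);
      uword B = stop - start;
      // gather batch: (B, k, T) and one-hot labels
      fcube Xb(B, k, T);
      fmat Y(B, 2, fill::zeros);
      for (uword b = 0; b < B; ++b) {
        uword idx = order[start + b];
        for (uword t = 0; t < T; ++t)
          for (uword j = 0; j < k; ++j)
            Xb(b, j, t) = (float)Xtr(t, j, idx);
        Y(b, (uword)ytr(idx)) = 1.0f;
      }
      // ---- forward ----
      LstmCache c1, c2;
      lstm_forward(Xb, net.par[0], net.par[1], net.par[2], c1);
      fcube M1(B, (uword)h1, T), H1d(B, (uword)h1, T);
      for (uword t = 0; t < T; ++t) {
        fmat Mt(B, (uword)h1);
        dropout_mask(Mt, drop1, rng);
        M1.slice(t) = Mt;
        H1d.slice(t) = c1.H.slice(t) % Mt;
      }
      lstm_forward(H1d, net.par[3], net.par[4], net.par[5], c2);
      fmat M2(B, (uword)h2);
      dropout_mask(M2, drop2, rng);
      fmat h2d = c2.H.slice(T - 1) % M2;
      fmat A3 = h2d * net.par[6];
      A3.each_row() += net.par[7];
      fmat Z3 = clamp(A3, 0.0f, std::numeric_limits<float>::max());
      fmat M3(B, (uword)d);
      dropout_mask(M3, drop3, rng);
      fmat Z3d = Z3 % M3;
      fmat logits = Z3d * net.par[8];
      logits.each_row() += net.par[9];
      fmat P = softmax_rows(logits);
      for (uword b = 0; b < B; ++b) {
        uword yy = (uword)ytr(order[start + b]);
        ep_loss -= std::log(std::max(P(b, yy), 1e-12f)) ;
        ep_correct += (P(b, 1) > P(b, 0)) == (yy == 1);
      }
      // ---- backward ----
      fmat dlogits = (P - Y) / (float)B;
      g[8] = Z3d.t() * dlogits;                 // W4
      g[9] = sum(dlogits, 0);                   // b4
      fmat dZ3 = (dlogits * net.par[8].t()) % M3;
      fmat dA3 = dZ3 % conv_to<fmat>::from(A3 > 0.0f);
      g[6] = h2d.t() * dA3;                     // W3
      g[7] = sum(dA3, 0);                       // b3
      fmat dh2T = (dA3 * net.par[6].t()) % M2;
      fcube dHin2(B, (uword)h2, T, fill::zeros);
      dHin2.slice(T - 1) = dh2T;
      fcube dX2;
      lstm_backward(H1d, c2, net.par[3], net.par[4], dHin2,
                    g[3], g[4], g[5], dX2);
      fcube dHin1(B, (uword)h1, T);
      for (uword t = 0; t < T; ++t)
        dHin1.slice(t) = dX2.slice(t) % M1.slice(t);
      fcube dX1;
      lstm_backward(Xb, c1, net.par[0], net.par[1], dHin1,
                    g[0], g[1], g[2], dX1);
      // L2 penalty on the LSTM input kernels
      if (l2 > 0) {
        g[0] += 2.0f * (float)l2 * net.par[0];
        g[3] += 2.0f * (float)l2 * net.par[3];
      }
      // ---- Adam update ----
      ++step;
      float c1b = 1.0f - std::pow(b1a, (float)step);
      float c2b = 1.0f - std::pow(b2a, (float)step);
      for (int i = 0; i < N_PAR; ++i) {
        m[i] = b1a * m[i] + (1.0f - b1a) * g[i];
        v[i] = b2a * v[i] + (1.0f - b2a) * square(g[i]);
        net.par[i] -= (float)lr * (m[i] / c1b) / (sqrt(v[i] / c2b) + eps);
      }
    }
    double train_loss = ep_loss / (double)n;
    if (l2 > 0)
      train_loss += l2 * (accu(square(net.par[0])) + accu(square(net.par[3])));
    double train_acc = ep_correct / (double)n;
    fmat Pv = eval_forward(net, Xval);
    double val_loss = 0;
    for (uword i = 0; i < yval.n_elem; ++i)
      val_loss -= std::log(std::max(Pv(i, (uword)yval(i)), 1e-12f));
    val_loss /= (double)yval.n_elem;
    double val_acc = val_accuracy(Pv, yval);
    history(epoch - 1, 0) = train_loss;
    history(epoch - 1, 1) = train_acc;
    history(epoch - 1, 2) = val_loss;
    history(epoch - 1, 3) = val_acc;
    epochs_run = epoch;
    if (val_acc > best_val) {        // strict: earliest epoch wins ties
      best_val = val_acc;
      best_epoch = epoch;
      best_par = net.par;
    }
    if (epoch - best_epoch >= patience) break;
    Rcpp::checkUserInterrupt();
  }
  net.par = best_par;
  Rcpp::List out = net_to_list(net);
  return Rcpp::List::create(
    Rcpp::Named("params") = out,
    Rcpp::Named("history") = history.rows(0, epochs_run - 1),
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("epochs_run") = epochs_run);
}
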