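// Feed-forward / BiLSTM network used by the chimeric deamidation models.
//
// Architecture (per site):
//   global branch : fixed pLM site vector g (d) -- frozen, an input here
//   local branch  : token window (w ids) -> trainable embedding (e) ->
//                   BiLSTM (hidden h per direction), final fwd/bwd states
//                   concatenated -> 2h vector
//   head          : concat(g, local) -> FC(H1) relu -> dropout ->
//                   FC(H2) relu -> dropout -> FC(out)
//   out = 1 sigmoid (classification, BCE) or 3 linear (regression, masked MSE
//   on extents scaled to [0,1]).
//
// Either branch can be absent (global_only / local_only variants). All
// randomness (shuffling, dropout) comes from R's RNG so training is
// reproducible under set.seed(). Optimiser: Adam.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::uvec;
using arma::vec;

static inline mat sigmoid_m(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }
static inline mat relu_m(const mat& x) { return arma::clamp(x, 0.0, arma::datum::inf); }

struct LstmDir {
  mat Wx, Wh;  // e x 4h, h x 4h  (gate order: i, f, g, o)
  arma::rowvec b;  // 1 x 4h
};

struct Net {
  bool use_global = false, use_local = false;
  bool classify = true;
  int e = 0, h = 0, V = 0, w = 0, d = 0, out = 1;
  mat Emb;          // V x e (row = token id + 1; id 0 is PAD)
  LstmDir fw, bw;
  mat W1, W2, W3;
  arma::rowvec b1, b2, b3;
};

static Net unpack(const List& weights) {
  Net n;
  n.use_global = as<bool>(weights["use_global"]);
  n.use_local = as<bool>(weights["use_local"]);
  n.classify = as<std::string>(weights["task"]) == "classification";
  n.d = as<int>(weights["d"]);
  if (n.use_local) {
    n.Emb = as<mat>(weights["Emb"]);
    n.V = n.Emb.n_rows; n.e = n.Emb.n_cols;
    n.fw.Wx = as<mat>(weights["Wxf"]); n.fw.Wh = as<mat>(weights["Whf"]);
    n.fw.b = as<arma::rowvec>(weights["bf"]);
    n.bw.Wx = as<mat>(weights["Wxb"]); n.bw.Wh = as<mat>(weights["Whb"]);
    n.bw.b = as<arma::rowvec>(weights["bb"]);
    n.h = n.fw.Wh.n_rows;
  }
  n.W1 = as<mat>(weights["W1"]); n.b1 = as<arma::rowvec>(weights["b1"]);
  n.W2 = as<mat>(weights["W2"]); n.b2 = as<arma::rowvec>(weights["b2"]);
  n.W3 = as<mat>(weights["W3"]); n.b3 = as<arma::rowvec>(weights["b3"]);
  n.out = n.W3.n_cols;
  return n;
}

static List pack(const Net& n, const List& proto) {
  List w = clone(proto);
  if (n.use_local) {
    w["Emb"] = n.Emb;
    w["Wxf"] = n.fw.Wx; w["Whf"] = n.fw.Wh; w["bf"] = n.fw.b;
    w["Wxb"] = n.bw.Wx; w["Whb"] = n.bw.Wh; w["bb"] = n.bw.b;
  }
  w["W1"] = n.W1; w["b1"] = n.b1;
  w["W2"] = n.W2; w["b2"] = n.b2;
  w["W3"] = n.W3; w["b3"] = n.b3;
  return w;
}

// Forward pass of one LSTM direction over the whole batch, keeping the
// per-step activations needed for backprop-through-time. The direction's
// window summary is the mean of its hidden states over all steps.
struct LstmTrace {
  std::vector<mat> i, f, g, o, c, tc, h_prev, c_prev, x;
  mat h_final;
};

static void lstm_forward(const LstmDir& L, const mat& Emb,
                         const arma::imat& tok, bool reverse,
                         LstmTrace& tr, bool keep_trace) {
  const int N = tok.n_rows, w = tok.n_cols, h = L.Wh.n_rows;
  mat H(N, h, arma::fill::zeros), C(N, h, arma::fill::zeros);
  mat Hsum(N, h, arma::fill::zeros);
  if (keep_trace) {
    tr.i.resize(w); tr.f.resize(w); tr.g.resize(w); tr.o.resize(w);
    tr.c.resize(w); tr.tc.resize(w); tr.h_prev.resize(w); tr.c_prev.resize(w);
    tr.x.resize(w);
  }
  for (int s = 0; s < w; ++s) {
    int t = reverse ? (w - 1 - s) : s;
    mat X(N, Emb.n_cols);
    for (int r = 0; r < N; ++r) X.row(r) = Emb.row(tok(r, t));
    mat gates = X * L.Wx + H * L.Wh;
    gates.each_row() += L.b;
    mat gi = sigmoid_m(gates.cols(0, h - 1));
    mat gf = sigmoid_m(gates.cols(h, 2 * h - 1));
    mat gg = arma::tanh(gates.cols(2 * h, 3 * h - 1));
    mat go = sigmoid_m(gates.cols(3 * h, 4 * h - 1));
    mat Cn = gf % C + gi % gg;
    mat tC = arma::tanh(Cn);
    if (keep_trace) {
      tr.i[s] = gi; tr.f[s] = gf; tr.g[s] = gg; tr.o[s] = go;
      tr.c[s] = Cn; tr.tc[s] = tC; tr.h_prev[s] = H; tr.c_prev[s] = C;
      tr.x[s] = X;
    }
    C = Cn;
    H = go % tC;
    Hsum += H;
  }
  tr.h_final = Hsum / (double)w;
}

// Backprop through one direction. dH_pool is the gradient at the mean-pooled
// summary; each step receives dH_pool / w plus the recurrent carry.
// Accumulates parameter gradients and the embedding-row gradients.
static void lstm_backward(const LstmDir& L, const LstmTrace& tr,
                          const arma::imat& tok, bool reverse, const mat& dH_pool,
                          mat& dWx, mat& dWh, arma::rowvec& db, mat& dEmb) {
  const int N = tok.n_rows, w = tok.n_cols, h = L.Wh.n_rows;
  mat dH_step = dH_pool / (double)w;
  mat dH = dH_step, dC(N, h, arma::fill::zeros);
  for (int s = w - 1; s >= 0; --s) {
    int t = reverse ? (w - 1 - s) : s;
    const mat &gi = tr.i[s], &gf = tr.f[s], &gg = tr.g[s], &go = tr.o[s];
    mat d_o = dH % tr.tc[s];
    dC += dH % go % (1.0 - arma::square(tr.tc[s]));
    mat d_i = dC % gg;
    mat d_f = dC % tr.c_prev[s];
    mat d_g = dC % gi;
    mat dg4(N, 4 * h);
    dg4.cols(0, h - 1)         = d_i % gi % (1.0 - gi);
    dg4.cols(h, 2 * h - 1)     = d_f % gf % (1.0 - gf);
    dg4.cols(2 * h, 3 * h - 1) = d_g % (1.0 - arma::square(gg));
    dg4.cols(3 * h, 4 * h - 1) = d_o % go % (1.0 - go);
    dWx += tr.x[s].t() * dg4;
    dWh += tr.h_prev[s].t() * dg4;
    db += arma::sum(dg4, 0);
    mat dX = dg4 * L.Wx.t();
    for (int r = 0; r < N; ++r) dEmb.row(tok(r, t)) += dX.row(r);
    dH = dg4 * L.Wh.t() + dH_step;
    dC = dC % gf;
  }
}

struct FwdTrace {
  LstmTrace fw, bw;
  mat Z, A1, A2, M1, M2, O;  // M1/M2 dropout masks (scaled)
};

// Full forward pass. dropout_p > 0 only during training.
static mat forward(const Net& n, const mat& G, const arma::imat& tok,
                   double dropout_p, FwdTrace* tr) {
  int N = n.use_global ? G.n_rows : tok.n_rows;
  mat Z;
  LstmTrace twf, twb;
  if (n.use_local) {
    lstm_forward(n.fw, n.Emb, tok, false, twf, tr != nullptr);
    lstm_forward(n.bw, n.Emb, tok, true, twb, tr != nullptr);
    mat Lv = arma::join_rows(twf.h_final, twb.h_final);
    Z = n.use_global ? arma::join_rows(G, Lv) : Lv;
  } else {
    Z = G;
  }
  mat A1 = relu_m(Z * n.W1 + arma::repmat(n.b1, N, 1));
  mat M1, M2;
  if (dropout_p > 0) {
    NumericVector u = runif(A1.n_elem);
    M1 = mat(u.begin(), A1.n_rows, A1.n_cols);
    M1 = arma::conv_to<mat>::from(M1 > dropout_p) / (1.0 - dropout_p);
    A1 = A1 % M1;
  }
  mat A2 = relu_m(A1 * n.W2 + arma::repmat(n.b2, N, 1));
  if (dropout_p > 0) {
    NumericVector u = runif(A2.n_elem);
    M2 = mat(u.begin(), A2.n_rows, A2.n_cols);
    M2 = arma::conv_to<mat>::from(M2 > dropout_p) / (1.0 - dropout_p);
    A2 = A2 % M2;
  }
  mat O = A2 * n.W3 + arma::repmat(n.b3, N, 1);
  if (n.classify) O = sigmoid_m(O);
  if (tr) {
    tr->fw = twf; tr->bw = twb; tr->Z = Z; tr->A1 = A1; tr->A2 = A2;
    tr->M1 = M1; tr->M2 = M2; tr->O = O;
  }
  return O;
}

// Loss: mean BCE with optional positive-class weight (classification) or
// masked MSE (regression; mask = finite Y).
static double loss_of(const Net& n, const mat& O, const mat& Y,
                      double pos_weight = 1.0) {
  if (n.classify) {
    mat P = arma::clamp(O, 1e-12, 1.0 - 1e-12);
    return arma::accu(-(pos_weight * Y % arma::log(P) +
                        (1.0 - Y) % arma::log(1.0 - P))) / Y.n_rows;
  }
  mat M = arma::conv_to<mat>::from(Y == Y);  // finite mask (NaN != NaN)
  mat Yz = Y; Yz.replace(arma::datum::nan, 0.0);
  double m = arma::accu(M);
  if (m < 1) return 0.0;
  return arma::accu(arma::square((O - Yz) % M)) / m;
}

struct Grads {
  mat Emb, Wxf, Whf, Wxb, Whb, W1, W2, W3;
  arma::rowvec bf, bb, b1, b2, b3;
};

static Grads zero_grads(const Net& n) {
  Grads g;
  if (n.use_local) {
    g.Emb.zeros(n.V, n.e);
    g.Wxf.zeros(n.e, 4 * n.h); g.Whf.zeros(n.h, 4 * n.h); g.bf.zeros(4 * n.h);
    g.Wxb.zeros(n.e, 4 * n.h); g.Whb.zeros(n.h, 4 * n.h); g.bb.zeros(4 * n.h);
  }
  g.W1.zeros(n.W1.n_rows, n.W1.n_cols); g.b1.zeros(n.b1.n_elem);
  g.W2.zeros(n.W2.n_rows, n.W2.n_cols); g.b2.zeros(n.b2.n_elem);
  g.W3.zeros(n.W3.n_rows, n.W3.n_cols); g.b3.zeros(n.b3.n_elem);
  return g;
}

static void backward(const Net& n, const FwdTrace& tr, const mat& G,
                     const arma::imat& tok, const mat& Y, Grads& g,
                     double pos_weight = 1.0) {
  int N = tr.O.n_rows;
  mat dO;
  if (n.classify) {
    // sigmoid + weighted BCE combined: pw*y*(P-1) + (1-y)*P
    dO = (pos_weight * Y % (tr.O - 1.0) + (1.0 - Y) % tr.O) / (double)N;
  } else {
    mat M = arma::conv_to<mat>::from(Y == Y);
    mat Yz = Y; Yz.replace(arma::datum::nan, 0.0);
    double m = std::max(1.0, arma::accu(M));
    dO = 2.0 * ((tr.O - Yz) % M) / m;
  }
  g.W3 += tr.A2.t() * dO;
  g.b3 += arma::sum(dO, 0);
  mat dA2 = dO * n.W3.t();
  if (!tr.M2.is_empty()) dA2 = dA2 % tr.M2;
  dA2 = dA2 % arma::conv_to<mat>::from(tr.A2 > 0);
  g.W2 += tr.A1.t() * dA2;
  g.b2 += arma::sum(dA2, 0);
  mat dA1 = dA2 * n.W2.t();
  if (!tr.M1.is_empty()) dA1 = dA1 % tr.M1;
  dA1 = dA1 % arma::conv_to<mat>::from(tr.A1 > 0);
  g.W1 += tr.Z.t() * dA1;
  g.b1 += arma::sum(dA1, 0);
  if (n.use_local) {
    mat dZ = dA1 * n.W1.t();
    int off = n.use_global ? n.d : 0;
    mat dLf = dZ.cols(off, off + n.h - 1);
    mat dLb = dZ.cols(off + n.h, off + 2 * n.h - 1);
    lstm_backward(n.fw, tr.fw, tok, false, dLf, g.Wxf, g.Whf, g.bf, g.Emb);
    lstm_backward(n.bw, tr.bw, tok, true, dLb, g.Wxb, g.Whb, g.bb, g.Emb);
  }
}

// Adam state kept as flat vectors over all trainable parameters.
struct Adam {
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  std::vector<mat*> params;
  std::vector<mat> m, v;
  std::vector<arma::rowvec*> rparams;
  std::vector<arma::rowvec> rm, rv;
  void attach(Net& n) {
    params.clear(); rparams.clear();
    if (n.use_local) {
      params = {&n.Emb, &n.fw.Wx, &n.fw.Wh, &n.bw.Wx, &n.bw.Wh,
                &n.W1, &n.W2, &n.W3};
      rparams = {&n.fw.b, &n.bw.b, &n.b1, &n.b2, &n.b3};
    } else {
      params = {&n.W1, &n.W2, &n.W3};
      rparams = {&n.b1, &n.b2, &n.b3};
    }
    for (auto* p : params) { m.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros)); v.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros)); }
    for (auto* p : rparams) { rm.push_back(arma::rowvec(p->n_elem, arma::fill::zeros)); rv.push_back(arma::rowvec(p->n_elem, arma::fill::zeros)); }
  }
  void step(const Net& n, const Grads& g) {
    ++t;
    std::vector<const mat*> gm;
    std::vector<const arma::rowvec*> gr;
    if (n.use_local) {
      gm = {&g.Emb, &g.Wxf, &g.Whf, &g.Wxb, &g.Whb, &g.W1, &g.W2, &g.W3};
      gr = {&g.bf, &g.bb, &g.b1, &g.b2, &g.b3};
    } else {
      gm = {&g.W1, &g.W2, &g.W3};
      gr = {&g.b1, &g.b2, &g.b3};
    }
    double c1 = 1.0 - std::pow(b1, (double)t), c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t k = 0; k < params.size(); ++k) {
      m[k] = b1 * m[k] + (1 - b1) * (*gm[k]);
      v[k] = b2 * v[k] + (1 - b2) * arma::square(*gm[k]);
      *params[k] -= lr * (m[k] / c1) / (arma::sqrt(v[k] / c2) + eps);
    }
    for (size_t k = 0; k < rparams.size(); ++k) {
      rm[k] = b1 * rm[k] + (1 - b1) * (*gr[k]);
      rv[k] = b2 * rv[k] + (1 - b2) * arma::square(*gr[k]);
      *rparams[k] -= lr * (rm[k] / c1) / (arma::sqrt(rv[k] / c2) + eps);
    }
  }
};

static arma::imat as_tok(SEXP x) {
  if (Rf_isNull(x)) return arma::imat();
  IntegerMatrix m(x);
  arma::imat out(m.nrow(), m.ncol());
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j) out(i, j) = m(i, j);
  return out;
}

static mat as_matd(SEXP x) {
  if (Rf_isNull(x)) return mat();
  return as<mat>(x);
}

// [[Rcpp::export]]
List nn_train_cpp(List weights, SEXP G_, SEXP tok_, NumericMatrix Y_,
                  SEXP Gv_, SEXP tokv_, NumericMatrix Yv_,
                  double lr, int batch, int max_epochs, int patience,
                  double dropout_p, double pos_weight) {
  Net n = unpack(weights);
  mat G = as_matd(G_), Gv = as_matd(Gv_);
  arma::imat tok = as_tok(tok_), tokv = as_tok(tokv_);
  mat Y(Y_.begin(), Y_.nrow(), Y_.ncol());
  mat Yv(Yv_.begin(), Yv_.nrow(), Yv_.ncol());
  const int N = Y.n_rows;
  Adam opt; opt.lr = lr; opt.attach(n);

  List best = pack(n, weights);
  double best_val = R_PosInf;
  int best_epoch = 0, wait = 0, epochs_run = 0;
  std::vector<double> tr_hist, val_hist;

  for (int ep = 1; ep <= max_epochs; ++ep) {
    IntegerVector perm = sample(N, N, false);  // R RNG, 1-based
    double ep_loss = 0; int nb = 0;
    for (int start = 0; start < N; start += batch) {
      int end = std::min(start + batch, N) - 1;
      uvec idx(end - start + 1);
      for (int k = start; k <= end; ++k) idx(k - start) = perm[k] - 1;
      mat Gb = n.use_global ? mat(G.rows(idx)) : mat();
      arma::imat tb;
      if (n.use_local) {
        tb.set_size(idx.n_elem, tok.n_cols);
        for (size_t r = 0; r < idx.n_elem; ++r) tb.row(r) = tok.row(idx(r));
      }
      mat Yb = Y.rows(idx);
      FwdTrace tr;
      mat O = forward(n, Gb, tb, dropout_p, &tr);
      ep_loss += loss_of(n, O, Yb, pos_weight); ++nb;
      Grads g = zero_grads(n);
      backward(n, tr, Gb, tb, Yb, g, pos_weight);
      opt.step(n, g);
    }
    epochs_run = ep;
    tr_hist.push_back(ep_loss / std::max(1, nb));
    mat Ov = forward(n, Gv, tokv, 0.0, nullptr);
    double vl = loss_of(n, Ov, Yv, pos_weight);
    val_hist.push_back(vl);
    if (vl < best_val - 1e-9) {
      best_val = vl; best_epoch = ep; wait = 0;
      best = pack(n, weights);
    } else {
      if (++wait > patience) break;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = best,
                      _["best_val_loss"] = best_val,
                      _["best_epoch"] = best_epoch,
                      _["epochs_run"] = epochs_run,
                      _["train_loss"] = tr_hist,
                      _["val_loss"] = val_hist);
}

// [[Rcpp::export]]
NumericMatrix nn_forward_cpp(List weights, SEXP G_, SEXP tok_) {
  Net n = unpack(weights);
  mat G = as_matd(G_);
  arma::imat tok = as_tok(tok_);
  mat O = forward(n, G, tok, 0.0, nullptr);
  return wrap(O);
}

// [[Rcpp::export]]
NumericMatrix nn_local_cpp(List weights, SEXP tok_) {
  Net n = unpack(weights);
  if (!n.use_local) stop("model has no local branch");
  arma::imat tok = as_tok(tok_);
  LstmTrace tf, tb;
  lstm_forward(n.fw, n.Emb, tok, false, tf, false);
  lstm_forward(n.bw, n.Emb, tok, true, tb, false);
  return wrap(arma::join_rows(tf.h_final, tb.h_final));
}
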