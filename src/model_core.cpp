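// Forward and backward passes of the parenting-style assessment network:
// two stacked LSTM layers over the post-embedding sequence, tanh attention
// pooling, concatenation with six lexicon-set representation vectors
// (correlation injection), and a two-layer tanh head emitting three
// normalized scores in (-1, 1). Gradients are analytic (BPTT); the training
// loop, optimiser and initialisation live in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::rowvec;
using arma::vec;

static inline mat sigmoid(const mat &x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct LstmCache {
  mat I, F, G, O, Cs, Tc, Hs; // n x H gate activations, cell states, tanh(c), outputs
};

// Gate column order within the 4H blocks: [input, forget, cell, output].
static mat lstm_forward(const mat &X, const mat &Wx, const mat &Wh,
                        const rowvec &b, LstmCache &cc) {
  const arma::uword n = X.n_rows, H = Wh.n_rows;
  cc.I.set_size(n, H); cc.F.set_size(n, H); cc.G.set_size(n, H);
  cc.O.set_size(n, H); cc.Cs.set_size(n, H); cc.Tc.set_size(n, H);
  cc.Hs.set_size(n, H);
  rowvec h(H, arma::fill::zeros), c(H, arma::fill::zeros);
  for (arma::uword t = 0; t < n; ++t) {
    rowvec a = X.row(t) * Wx + h * Wh + b;
    rowvec i = sigmoid(a.cols(0, H - 1));
    rowvec f = sigmoid(a.cols(H, 2 * H - 1));
    rowvec g = arma::tanh(a.cols(2 * H, 3 * H - 1));
    rowvec o = sigmoid(a.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    rowvec tc = arma::tanh(c);
    h = o % tc;
    cc.I.row(t) = i; cc.F.row(t) = f; cc.G.row(t) = g; cc.O.row(t) = o;
    cc.Cs.row(t) = c; cc.Tc.row(t) = tc; cc.Hs.row(t) = h;
  }
  return cc.Hs;
}

// dHout: upstream gradient on each hidden output row. Accumulates parameter
// gradients and returns the gradient w.r.t. the layer input X.
static mat lstm_backward(const mat &X, const mat &Wx, const mat &Wh,
                         const LstmCache &cc, const mat &dHout,
                         mat &dWx, mat &dWh, rowvec &db) {
  const arma::uword n = X.n_rows, H = Wh.n_rows;
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  db.zeros(4 * H);
  mat dX(n, X.n_cols, arma::fill::zeros);
  rowvec dh_next(H, arma::fill::zeros), dc_next(H, arma::fill::zeros);
  for (arma::uword s = n; s-- > 0;) {
    rowvec i = cc.I.row(s), f = cc.F.row(s), g = cc.G.row(s), o = cc.O.row(s);
    rowvec tc = cc.Tc.row(s);
    rowvec c_prev = (s == 0) ? rowvec(H, arma::fill::zeros) : rowvec(cc.Cs.row(s - 1));
    rowvec h_prev = (s == 0) ? rowvec(H, arma::fill::zeros) : rowvec(cc.Hs.row(s - 1));
    rowvec dh = dHout.row(s) + dh_next;
    rowvec dc = dh % o % (1.0 - tc % tc) + dc_next;
    rowvec da(4 * H);
    da.cols(0, H - 1)         = (dc % g) % i % (1.0 - i);
    da.cols(H, 2 * H - 1)     = (dc % c_prev) % f % (1.0 - f);
    da.cols(2 * H, 3 * H - 1) = (dc % i) % (1.0 - g % g);
    da.cols(3 * H, 4 * H - 1) = (dh % tc) % o % (1.0 - o);
    dWx += X.row(s).t() * da;
    dWh += h_prev.t() * da;
    db += da;
    dX.row(s) = da * Wx.t();
    dh_next = da * Wh.t();
    dc_next = dc % f;
  }
  return dX;
}

struct Params {
  mat l1Wx, l1Wh, l2Wx, l2Wh, attW, fc1W, fc2W;
  rowvec l1b, l2b, fc1b, fc2b;
  double attb;
};

static Params unpack(const Rcpp::List &p) {
  Params q;
  q.l1Wx = Rcpp::as<mat>(p["lstm1_Wx"]); q.l1Wh = Rcpp::as<mat>(p["lstm1_Wh"]);
  q.l1b  = Rcpp::as<rowvec>(p["lstm1_b"]);
  q.l2Wx = Rcpp::as<mat>(p["lstm2_Wx"]); q.l2Wh = Rcpp::as<mat>(p["lstm2_Wh"]);
  q.l2b  = Rcpp::as<rowvec>(p["lstm2_b"]);
  q.attW = Rcpp::as<mat>(p["att_W"]);
  q.attb = Rcpp::as<double>(p["att_b"]);
  q.fc1W = Rcpp::as<mat>(p["fc1_W"]); q.fc1b = Rcpp::as<rowvec>(p["fc1_b"]);
  q.fc2W = Rcpp::as<mat>(p["fc2_W"]); q.fc2b = Rcpp::as<rowvec>(p["fc2_b"]);
  return q;
}

struct Trace {
  mat H;                    // n x H hidden sequence (layer 2)
  vec att;                  // n raw tanh attention scores
  rowvec Hp, C, U, scores;  // pooled vector, concat, head hidden, outputs
  LstmCache c1, c2;
};

static void forward_core(const mat &emb, const rowvec &reps, const Params &q,
                         bool no_attention, bool no_injection, Trace &tr) {
  tr.H = lstm_forward(emb, q.l1Wx, q.l1Wh, q.l1b, tr.c1);
  tr.H = lstm_forward(tr.H, q.l2Wx, q.l2Wh, q.l2b, tr.c2);
  const arma::uword n = tr.H.n_rows;
  if (no_attention) {
    tr.att = vec(n, arma::fill::value(1.0 / n));
    tr.Hp = arma::mean(tr.H, 0);
  } else {
    tr.att = arma::tanh(tr.H * q.attW + q.attb);
    tr.Hp = tr.att.t() * tr.H;
  }
  tr.C = no_injection ? tr.Hp : arma::join_rows(tr.Hp, reps);
  tr.U = arma::tanh(tr.C * q.fc1W + q.fc1b);
  tr.scores = arma::tanh(tr.U * q.fc2W + q.fc2b);
}

// [[Rcpp::export]]
Rcpp::List cpp_forward(const arma::mat &emb, const arma::rowvec &reps,
                       const Rcpp::List &params, bool no_attention,
                       bool no_injection) {
  Params q = unpack(params);
  Trace tr;
  forward_core(emb, reps, q, no_attention, no_injection, tr);
  return Rcpp::List::create(
      Rcpp::Named("H") = tr.H,
      Rcpp::Named("att") = tr.att,
      Rcpp::Named("pooled") = tr.Hp,
      Rcpp::Named("concat") = tr.C,
      Rcpp::Named("head_hidden") = tr.U,
      Rcpp::Named("scores") = tr.scores);
}

// Accumulate gradients of the per-user loss mean_k (scores_k - y_k)^2 into g*.
static double backward_core(const mat &emb, const rowvec &reps, const Params &q,
                            bool no_attention, bool no_injection,
                            const rowvec &y, Params &g) {
  Trace tr;
  forward_core(emb, reps, q, no_attention, no_injection, tr);
  const arma::uword n = tr.H.n_rows, H = tr.H.n_cols;
  rowvec diff = tr.scores - y;
  double loss = arma::accu(diff % diff) / 3.0;

  rowvec ds_pre = (2.0 / 3.0) * diff % (1.0 - tr.scores % tr.scores);
  g.fc2W += tr.U.t() * ds_pre;
  g.fc2b += ds_pre;
  rowvec dU = ds_pre * q.fc2W.t();
  rowvec du_pre = dU % (1.0 - tr.U % tr.U);
  g.fc1W += tr.C.t() * du_pre;
  g.fc1b += du_pre;
  rowvec dC = du_pre * q.fc1W.t();
  rowvec dHp = dC.cols(0, H - 1); // injection slots carry constants: no grad

  mat dH(n, H);
  if (no_attention) {
    dH.each_row() = dHp / static_cast<double>(n);
  } else {
    for (arma::uword t = 0; t < n; ++t) {
      double e = tr.att(t);
      double de = arma::dot(dHp, tr.H.row(t));
      double da = de * (1.0 - e * e);
      dH.row(t) = e * dHp + da * q.attW.t();
      g.attW += tr.H.row(t).t() * da;
      g.attb += da;
    }
  }

  mat dWx2, dWh2; rowvec db2;
  mat dH1 = lstm_backward(tr.c1.Hs, q.l2Wx, q.l2Wh, tr.c2, dH, dWx2, dWh2, db2);
  g.l2Wx += dWx2; g.l2Wh += dWh2; g.l2b += db2;
  mat dWx1, dWh1; rowvec db1;
  lstm_backward(emb, q.l1Wx, q.l1Wh, tr.c1, dH1, dWx1, dWh1, db1);
  g.l1Wx += dWx1; g.l1Wh += dWh1; g.l1b += db1;
  return loss;
}

static Params zero_like(const Params &q) {
  Params g;
  g.l1Wx.zeros(arma::size(q.l1Wx)); g.l1Wh.zeros(arma::size(q.l1Wh));
  g.l1b.zeros(q.l1b.n_elem);
  g.l2Wx.zeros(arma::size(q.l2Wx)); g.l2Wh.zeros(arma::size(q.l2Wh));
  g.l2b.zeros(q.l2b.n_elem);
  g.attW.zeros(arma::size(q.attW)); g.attb = 0.0;
  g.fc1W.zeros(arma::size(q.fc1W)); g.fc1b.zeros(q.fc1b.n_elem);
  g.fc2W.zeros(arma::size(q.fc2W)); g.fc2b.zeros(q.fc2b.n_elem);
  return g;
}

static Rcpp::List pack_grads(const Params &g) {
  return Rcpp::List::create(
      Rcpp::Named("lstm1_Wx") = g.l1Wx, Rcpp::Named("lstm1_Wh") = g.l1Wh,
      Rcpp::Named("lstm1_b") = g.l1b,
      Rcpp::Named("lstm2_Wx") = g.l2Wx, Rcpp::Named("lstm2_Wh") = g.l2Wh,
      Rcpp::Named("lstm2_b") = g.l2b,
      Rcpp::Named("att_W") = g.attW, Rcpp::Named("att_b") = g.attb,
      Rcpp::Named("fc1_W") = g.fc1W, Rcpp::Named("fc1_b") = g.fc1b,
      Rcpp::Named("fc2_W") = g.fc2W, Rcpp::Named("fc2_b") = g.fc2b);
}

// Mean loss and mean gradients over a batch of users (variable-length
// sequences, processed one by one — the exact equivalent of padding with
// masked steps excluded).
// [[Rcpp::export]]
Rcpp::List cpp_batch_loss_grad(const Rcpp::List &embs, const arma::mat &Y,
                               const arma::rowvec &reps, const Rcpp::List &params,
                               bool no_attention, bool no_injection) {
  Params q = unpack(params);
  Params g = zero_like(q);
  const int m = embs.size();
  double loss = 0.0;
  for (int u = 0; u < m; ++u) {
    mat emb = Rcpp::as<mat>(embs[u]);
    loss += backward_core(emb, reps, q, no_attention, no_injection, Y.row(u), g);
  }
  const double inv = 1.0 / m;
  g.l1Wx *= inv; g.l1Wh *= inv; g.l1b *= inv;
  g.l2Wx *= inv; g.l2Wh *= inv; g.l2b *= inv;
  g.attW *= inv; g.attb *= inv;
  g.fc1W *= inv; g.fc1b *= inv; g.fc2W *= inv; g.fc2b *= inv;
  return Rcpp::List::create(Rcpp::Named("loss") = loss * inv,
                            Rcpp::Named("grads") = pack_grads(g));
}

// [[Rcpp::export]]
arma::mat cpp_predict_batch(const Rcpp::List &embs, const arma::rowvec &reps,
                            const Rcpp::List &params, bool no_attention,
                            bool no_injection) {
  Params q = unpack(params);
  const int m = embs.size();
  mat out(m, 3);
  for (int u = 0; u < m; ++u) {
    Trace tr;
    forward_core(Rcpp::as<mat>(embs[u]), reps, q, no_attention, no_injection, tr);
    out.row(u) = tr.scores;
  }
  return out;
}
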