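// Fused forward/backward pass over the attention layer stack.
//
// The layer stack is post-norm transformer encoder blocks:
//   X1 = LN(X + MultiHeadAttention(X));  X2 = LN(X1 + FFN(X1))
// with a GELU feed-forward activation (sigmoid approximation,
// x * sigmoid(1.702 x), used consistently in forward and backward).
// Examples are ragged: X stacks all rows of a mini-batch; ex_start /
// ex_len delimit examples, and attention never crosses example
// boundaries. Rows with mask == 0 are excluded from the attention key
// set, so padding cannot influence any unmasked row.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double GELU_A = 1.702;
static const double LN_EPS = 1e-6;

struct LayerParams {
  arma::mat Wq, Wk, Wv, Wo, W1, W2;
  arma::rowvec bq, bk, bv, bo, b1, b2, ln1_g, ln1_b, ln2_g, ln2_b;
};

static LayerParams get_layer(const List& lp) {
  LayerParams p;
  p.Wq = as<arma::mat>(lp["Wq"]);  p.Wk = as<arma::mat>(lp["Wk"]);
  p.Wv = as<arma::mat>(lp["Wv"]);  p.Wo = as<arma::mat>(lp["Wo"]);
  p.W1 = as<arma::mat>(lp["W1"]);  p.W2 = as<arma::mat>(lp["W2"]);
  p.bq = as<arma::rowvec>(lp["bq"]); p.bk = as<arma::rowvec>(lp["bk"]);
  p.bv = as<arma::rowvec>(lp["bv"]); p.bo = as<arma::rowvec>(lp["bo"]);
  p.b1 = as<arma::rowvec>(lp["b1"]); p.b2 = as<arma::rowvec>(lp["b2"]);
  p.ln1_g = as<arma::rowvec>(lp["ln1_g"]); p.ln1_b = as<arma::rowvec>(lp["ln1_b"]);
  p.ln2_g = as<arma::rowvec>(lp["ln2_g"]); p.ln2_b = as<arma::rowvec>(lp["ln2_b"]);
  return p;
}

static void layernorm_fwd(const arma::mat& x, const arma::rowvec& g,
                          const arma::rowvec& b, arma::mat& xhat,
                          arma::vec& inv, arma::mat& y) {
  arma::vec mu = arma::mean(x, 1);
  xhat = x.each_col() - mu;
  inv = 1.0 / arma::sqrt(arma::mean(xhat % xhat, 1) + LN_EPS);
  xhat.each_col() %= inv;
  y = xhat.each_row() % g;
  y.each_row() += b;
}

static void layernorm_bwd(const arma::mat& dy, const arma::mat& xhat,
                          const arma::vec& inv, const arma::rowvec& g,
                          arma::mat& dx, arma::rowvec& dg, arma::rowvec& db) {
  dg = arma::sum(dy % xhat, 0);
  db = arma::sum(dy, 0);
  arma::mat dxhat = dy.each_row() % g;
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % xhat, 1);
  dx = dxhat;
  dx.each_col() -= m1;
  arma::mat t2 = xhat;
  t2.each_col() %= m2;
  dx -= t2;
  dx.each_col() %= inv;
}

// [[Rcpp::export(name = ".enc_layers_fwd")]]
List enc_layers_fwd(List layer_params, const arma::mat& X0,
                    const arma::ivec& ex_start, const arma::ivec& ex_len,
                    int num_heads, int head_dim,
                    const arma::ivec& mask, bool keep_cache) {
  int L = layer_params.size();
  int B = ex_start.n_elem;
  double scale = 1.0 / std::sqrt((double)head_dim);
  arma::mat X = X0;
  List caches(L);

  // per-example key indices (mask == 1 rows)
  std::vector<arma::uvec> kidx(B), qidx(B);
  for (int b = 0; b < B; ++b) {
    int s = ex_start[b], n = ex_len[b];
    arma::uvec rows = arma::regspace<arma::uvec>(s, s + n - 1);
    qidx[b] = rows;
    std::vector<arma::uword> keep;
    keep.reserve(n);
    for (int j = 0; j < n; ++j) if (mask[s + j] == 1) keep.push_back(s + j);
    kidx[b] = arma::uvec(keep);
    if (kidx[b].n_elem == 0) stop("example %d has no unmasked rows", b + 1);
  }

  for (int l = 0; l < L; ++l) {
    LayerParams p = get_layer(layer_params[l]);
    arma::mat X_in = X;
    arma::mat Q = X * p.Wq; Q.each_row() += p.bq;
    arma::mat K = X * p.Wk; K.each_row() += p.bk;
    arma::mat V = X * p.Wv; V.each_row() += p.bv;
    arma::mat AO(X.n_rows, X.n_cols, arma::fill::zeros);
    List Pmats(keep_cache ? B : 0);
    for (int b = 0; b < B; ++b) {
      List Pb(keep_cache ? num_heads : 0);
      bool padded = kidx[b].n_elem != qidx[b].n_elem;
      arma::span rows(qidx[b].front(), qidx[b].back());
      for (int h = 0; h < num_heads; ++h) {
        arma::span cols(h * head_dim, (h + 1) * head_dim - 1);
        arma::mat Kb = padded ? arma::mat(K(kidx[b], arma::regspace<arma::uvec>(
                          h * head_dim, (h + 1) * head_dim - 1)))
                              : arma::mat(K(rows, cols));
        arma::mat Vb = padded ? arma::mat(V(kidx[b], arma::regspace<arma::uvec>(
                          h * head_dim, (h + 1) * head_dim - 1)))
                              : arma::mat(V(rows, cols));
        arma::mat S = Q(rows, cols) * Kb.t() * scale;
        arma::vec mx = arma::max(S, 1);
        S.each_col() -= mx;
        S = arma::exp(S);
        S.each_col() /= arma::sum(S, 1);
        AO(rows, cols) = S * Vb;
        if (keep_cache) Pb[h] = S;
      }
      if (keep_cache) Pmats[b] = Pb;
    }
    arma::mat O = AO * p.Wo; O.each_row() += p.bo;
    arma::mat xhat1, xhat2, X1, X2;
    arma::vec inv1, inv2;
    layernorm_fwd(X_in + O, p.ln1_g, p.ln1_b, xhat1, inv1, X1);
    arma::mat Hpre = X1 * p.W1; Hpre.each_row() += p.b1;
    arma::mat Sg = 1.0 / (1.0 + arma::exp(-GELU_A * Hpre));
    arma::mat Hact = Hpre % Sg;
    arma::mat F2 = Hact * p.W2; F2.each_row() += p.b2;
    layernorm_fwd(X1 + F2, p.ln2_g, p.ln2_b, xhat2, inv2, X2);
    if (!X2.is_finite())
      stop("non-finite activations in encoder layer %d", l + 1);
    X = X2;
    if (keep_cache)
      caches[l] = List::create(
        _["X_in"] = X_in, _["Q"] = Q, _["K"] = K, _["V"] = V, _["AO"] = AO,
        _["Pmats"] = Pmats, _["xhat1"] = xhat1, _["inv1"] = inv1,
        _["X1"] = X1, _["Hpre"] = Hpre, _["Sg"] = Sg, _["xhat2"] = xhat2,
        _["inv2"] = inv2);
  }
  return List::create(_["X"] = X, _["caches"] = caches);
}

struct LayerCache {
  arma::mat X_in, Q, K, V, AO, xhat1, X1, Hpre, Sg, xhat2;
  arma::vec inv1, inv2;
  std::vector<arma::mat> P;  // B * num_heads softmax matrices
};

// One full training step over the layer stack and prediction head:
// forward with local caches, loss, and backward. Returns the loss, the
// predictions, gradients for every layer and head parameter, and the
// gradient with respect to the assembled input rows (for the pooling
// layers, whose parameters live on the R side).
// [[Rcpp::export(name = ".enc_train_step")]]
List enc_train_step(List layer_params, List head_params, const arma::mat& X0,
                    const arma::ivec& ex_start, const arma::ivec& ex_len,
                    int num_heads, int head_dim, const arma::uvec& cls_rows,
                    const arma::vec& y, bool classification) {
  int L = layer_params.size();
  int B = ex_start.n_elem;
  double scale = 1.0 / std::sqrt((double)head_dim);
  std::vector<LayerParams> pars(L);
  for (int l = 0; l < L; ++l) pars[l] = get_layer(layer_params[l]);
  std::vector<LayerCache> cache(L);
  // ---- forward ----
  arma::mat X = X0;
  for (int l = 0; l < L; ++l) {
    LayerParams& p = pars[l];
    LayerCache& cc = cache[l];
    cc.X_in = X;
    cc.Q = X * p.Wq; cc.Q.each_row() += p.bq;
    cc.K = X * p.Wk; cc.K.each_row() += p.bk;
    cc.V = X * p.Wv; cc.V.each_row() += p.bv;
    cc.AO.zeros(X.n_rows, X.n_cols);
    cc.P.resize(B * num_heads);
    for (int b = 0; b < B; ++b) {
      arma::span rows(ex_start[b], ex_start[b] + ex_len[b] - 1);
      for (int h = 0; h < num_heads; ++h) {
        arma::span cols(h * head_dim, (h + 1) * head_dim - 1);
        arma::mat S = cc.Q(rows, cols) * cc.K(rows, cols).t() * scale;
        arma::vec mx = arma::max(S, 1);
        S.each_col() -= mx;
        S = arma::exp(S);
        S.each_col() /= arma::sum(S, 1);
        cc.AO(rows, cols) = S * cc.V(rows, cols);
        cc.P[b * num_heads + h] = std::move(S);
      }
    }
    arma::mat O = cc.AO * p.Wo; O.each_row() += p.bo;
    layernorm_fwd(cc.X_in + O, p.ln1_g, p.ln1_b, cc.xhat1, cc.inv1, cc.X1);
    cc.Hpre = cc.X1 * p.W1; cc.Hpre.each_row() += p.b1;
    cc.Sg = 1.0 / (1.0 + arma::exp(-GELU_A * cc.Hpre));
    arma::mat F2 = (cc.Hpre % cc.Sg) * p.W2; F2.each_row() += p.b2;
    arma::mat X2;
    layernorm_fwd(cc.X1 + F2, p.ln2_g, p.ln2_b, cc.xhat2, cc.inv2, X2);
    if (!X2.is_finite())
      stop("non-finite activations in encoder layer %d", l + 1);
    X = std::move(X2);
  }

  // ---- prediction head + loss ----
  arma::mat hW1 = as<arma::mat>(head_params["head_W1"]);
  arma::rowvec hb1 = as<arma::rowvec>(head_params["head_b1"]);
  arma::mat hW2 = as<arma::mat>(head_params["head_W2"]);
  double hb2 = as<double>(head_params["head_b2"]);
  arma::mat C = X.rows(cls_rows);
  arma::mat h1pre = C * hW1; h1pre.each_row() += hb1;
  arma::mat h1 = h1pre;
  h1.elem(arma::find(h1pre < 0)).zeros();
  arma::vec out = h1 * hW2 + hb2;
  arma::vec pred = out, dout;
  double loss;
  if (classification) {
    pred = 1.0 / (1.0 + arma::exp(-out));
    arma::vec pc = arma::clamp(pred, 1e-12, 1.0 - 1e-12);
    loss = -arma::mean(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc));
    dout = (pred - y) / (double)B;
  } else {
    loss = arma::mean(arma::square(pred - y));
    dout = 2.0 * (pred - y) / (double)B;
  }
  arma::mat dh1 = dout * hW2.t();
  dh1.elem(arma::find(h1pre < 0)).zeros();
  List head_grads = List::create(
    _["head_W1"] = C.t() * dh1, _["head_b1"] = arma::sum(dh1, 0),
    _["head_W2"] = h1.t() * dout, _["head_b2"] = arma::accu(dout));
  arma::mat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  dX.rows(cls_rows) = dh1 * hW1.t();

  // ---- backward through the layers ----
  List grads(L);
  for (int l = L - 1; l >= 0; --l) {
    LayerParams& p = pars[l];
    LayerCache& cc = cache[l];
    arma::mat dR2;
    arma::rowvec dg2, db2n;
    layernorm_bwd(dX, cc.xhat2, cc.inv2, p.ln2_g, dR2, dg2, db2n);
    arma::mat Hact = cc.Hpre % cc.Sg;
    arma::mat dHact = dR2 * p.W2.t();
    arma::mat dW2 = Hact.t() * dR2;
    arma::rowvec db2 = arma::sum(dR2, 0);
    arma::mat dHpre = dHact %
      (cc.Sg + GELU_A * cc.Hpre % cc.Sg % (1.0 - cc.Sg));
    arma::mat dW1 = cc.X1.t() * dHpre;
    arma::rowvec db1 = arma::sum(dHpre, 0);
    arma::mat dX1 = dR2 + dHpre * p.W1.t();
    arma::mat dR1;
    arma::rowvec dg1, db1n;
    layernorm_bwd(dX1, cc.xhat1, cc.inv1, p.ln1_g, dR1, dg1, db1n);
    arma::mat dWo = cc.AO.t() * dR1;
    arma::rowvec dbo = arma::sum(dR1, 0);
    arma::mat dAO = dR1 * p.Wo.t();

    arma::mat dQ(dX.n_rows, dX.n_cols, arma::fill::zeros);
    arma::mat dK(dX.n_rows, dX.n_cols, arma::fill::zeros);
    arma::mat dV(dX.n_rows, dX.n_cols, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      arma::span rows(ex_start[b], ex_start[b] + ex_len[b] - 1);
      for (int h = 0; h < num_heads; ++h) {
        arma::span cols(h * head_dim, (h + 1) * head_dim - 1);
        arma::mat& P = cc.P[b * num_heads + h];
        arma::mat dAOb = dAO(rows, cols);
        arma::mat dP = dAOb * cc.V(rows, cols).t();
        dV(rows, cols) += P.t() * dAOb;
        arma::mat tmp = dP;
        tmp.each_col() -= arma::sum(dP % P, 1);
        arma::mat dS = (P % tmp) * scale;
        dQ(rows, cols) += dS * cc.K(rows, cols);
        dK(rows, cols) += dS.t() * cc.Q(rows, cols);
      }
    }
    grads[l] = List::create(
      _["Wq"] = cc.X_in.t() * dQ, _["Wk"] = cc.X_in.t() * dK,
      _["Wv"] = cc.X_in.t() * dV, _["Wo"] = dWo,
      _["bq"] = arma::sum(dQ, 0), _["bk"] = arma::sum(dK, 0),
      _["bv"] = arma::sum(dV, 0), _["bo"] = dbo,
      _["ln1_g"] = dg1, _["ln1_b"] = db1n, _["W1"] = dW1, _["b1"] = db1,
      _["W2"] = dW2, _["b2"] = db2, _["ln2_g"] = dg2, _["ln2_b"] = db2n);
    dX = dR1 + dQ * p.Wq.t() + dK * p.Wk.t() + dV * p.Wv.t();
  }
  return List::create(_["loss"] = loss, _["pred"] = pred, _["dX"] = dX,
                      _["grads"] = grads, _["head_grads"] = head_grads);
}
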