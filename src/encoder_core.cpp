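// Fast batch step for the transformer sentence encoder.
//
// This mirrors, operation for operation, the reference implementation in
// R/encoder.R (pre-norm attention blocks, logistic-approximation GELU,
// masked mean pooling, dropout + linear head); the test suite asserts the
// two paths agree.  Only the per-batch forward/backward is in C++ -- RNG,
// optimizer and control flow stay in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

namespace {

const double LN_EPS = 1e-5;

struct LnCache {
  mat xhat;
  vec istd;
};

mat ln_fwd(const mat& X, const rowvec& g, const rowvec& b, LnCache& cc) {
  vec mu = arma::mean(X, 1);
  mat Xc = X.each_col() - mu;
  cc.istd = 1.0 / arma::sqrt(arma::mean(Xc % Xc, 1) + LN_EPS);
  cc.xhat = Xc.each_col() % cc.istd;
  mat out = cc.xhat.each_row() % g;
  out.each_row() += b;
  return out;
}

mat ln_bwd(const mat& dy, const LnCache& cc, const rowvec& g,
           rowvec& dg, rowvec& db) {
  mat dxhat = dy.each_row() % g;
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % cc.xhat, 1);
  dg = arma::sum(dy % cc.xhat, 0);
  db = arma::sum(dy, 0);
  mat dx = dxhat.each_col() - m1;
  dx -= cc.xhat.each_col() % m2;
  dx.each_col() %= cc.istd;
  return dx;
}

mat gelu(const mat& x) {
  mat s = 1.0 / (1.0 + arma::exp(-1.702 * x));
  return x % s;
}

mat gelu_grad(const mat& x) {
  mat s = 1.0 / (1.0 + arma::exp(-1.702 * x));
  return s % (1.0 + 1.702 * x % (1.0 - s));
}

void softmax_rows_inplace(mat& S) {
  vec m = arma::max(S, 1);
  S.each_col() -= m;
  S = arma::exp(S);
  vec rs = arma::sum(S, 1);
  S.each_col() /= rs;
}

struct LayerCache {
  LnCache ln1, ln2;
  mat A, Q, K, V, O, M, H1, G;
  std::vector<std::vector<mat>> attn;  // [example][head]
};

std::string lname(int l, const char* nm) {
  return "L" + std::to_string(l + 1) + "." + nm;
}

}  // namespace

// Forward pass and, optionally, gradients of the weight-normalized batch
// cross entropy.  ids: B x T (1-based token ids, PAD = 1); yidx 1-based
// class index (1 absent, 2 present).  dmask: B x hidden dropout factors
// (ignored unless use_dropout).
// [[Rcpp::export]]
List enc_batch(const List& params, const IntegerMatrix& ids_,
               const IntegerVector& nreal_, int n_layers, int n_heads,
               const NumericMatrix& dmask_, bool use_dropout,
               const IntegerVector& yidx_, const NumericVector& cw_,
               bool do_backward) {
  const int B = ids_.nrow(), T = ids_.ncol();
  const mat emb = as<mat>(params["emb"]);
  const mat pos = as<mat>(params["pos"]);
  const int d = emb.n_cols;
  const int dh = d / n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  const int N = B * T;

  arma::uvec flat_ids(N);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t)
      flat_ids[b * T + t] = (arma::uword)(ids_(b, t) - 1);

  mat X(N, d);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t)
      X.row(b * T + t) = emb.row(flat_ids[b * T + t]) + pos.row(t);

  std::vector<LayerCache> caches(n_layers);
  std::vector<mat> Wq(n_layers), Wk(n_layers), Wv(n_layers), Wo(n_layers),
      W1(n_layers), W2(n_layers);
  std::vector<rowvec> bq(n_layers), bk(n_layers), bv(n_layers), bo(n_layers),
      b1(n_layers), b2(n_layers), ln1g(n_layers), ln1b(n_layers),
      ln2g(n_layers), ln2b(n_layers);
  std::vector<mat> Xin(n_layers), X1s(n_layers);

  for (int l = 0; l < n_layers; ++l) {
    Wq[l] = as<mat>(params[lname(l, "Wq")]);
    Wk[l] = as<mat>(params[lname(l, "Wk")]);
    Wv[l] = as<mat>(params[lname(l, "Wv")]);
    Wo[l] = as<mat>(params[lname(l, "Wo")]);
    W1[l] = as<mat>(params[lname(l, "W1")]);
    W2[l] = as<mat>(params[lname(l, "W2")]);
    bq[l] = as<rowvec>(params[lname(l, "bq")]);
    bk[l] = as<rowvec>(params[lname(l, "bk")]);
    bv[l] = as<rowvec>(params[lname(l, "bv")]);
    bo[l] = as<rowvec>(params[lname(l, "bo")]);
    b1[l] = as<rowvec>(params[lname(l, "b1")]);
    b2[l] = as<rowvec>(params[lname(l, "b2")]);
    ln1g[l] = as<rowvec>(params[lname(l, "ln1g")]);
    ln1b[l] = as<rowvec>(params[lname(l, "ln1b")]);
    ln2g[l] = as<rowvec>(params[lname(l, "ln2g")]);
    ln2b[l] = as<rowvec>(params[lname(l, "ln2b")]);

    LayerCache& cc = caches[l];
    Xin[l] = X;
    cc.A = ln_fwd(X, ln1g[l], ln1b[l], cc.ln1);
    cc.Q = cc.A * Wq[l]; cc.Q.each_row() += bq[l];
    cc.K = cc.A * Wk[l]; cc.K.each_row() += bk[l];
    cc.V = cc.A * Wv[l]; cc.V.each_row() += bv[l];
    cc.O.zeros(N, d);
    cc.attn.resize(B);
    for (int b = 0; b < B; ++b) {
      const int nr = nreal_[b];
      const int r0 = b * T;
      cc.attn[b].resize(n_heads);
      for (int h = 0; h < n_heads; ++h) {
        const int c0 = h * dh;
        mat S = cc.Q.submat(r0, c0, r0 + nr - 1, c0 + dh - 1) *
                cc.K.submat(r0, c0, r0 + nr - 1, c0 + dh - 1).t() * scale;
        softmax_rows_inplace(S);
        cc.attn[b][h] = S;
        cc.O.submat(r0, c0, r0 + nr - 1, c0 + dh - 1) =
            S * cc.V.submat(r0, c0, r0 + nr - 1, c0 + dh - 1);
      }
    }
    mat AO = cc.O * Wo[l]; AO.each_row() += bo[l];
    mat X1 = X + AO;
    X1s[l] = X1;
    cc.M = ln_fwd(X1, ln2g[l], ln2b[l], cc.ln2);
    cc.H1 = cc.M * W1[l]; cc.H1.each_row() += b1[l];
    cc.G = gelu(cc.H1);
    mat FF = cc.G * W2[l]; FF.each_row() += b2[l];
    X = X1 + FF;
  }

  const rowvec lnfg = as<rowvec>(params["lnfg"]);
  const rowvec lnfb = as<rowvec>(params["lnfb"]);
  LnCache lnf;
  mat Y = ln_fwd(X, lnfg, lnfb, lnf);

  mat pooled(B, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int nr = nreal_[b];
    pooled.row(b) =
        arma::sum(Y.rows(b * T, b * T + nr - 1), 0) / (double)nr;
  }
  mat pd = pooled;
  if (use_dropout) pd %= as<mat>(dmask_);

  const mat Wc = as<mat>(params["Wc"]);
  const rowvec bc = as<rowvec>(params["bc"]);
  mat logits = pd * Wc;
  logits.each_row() += bc;

  if (!do_backward) {
    return List::create(Named("logits") = logits);
  }

  // weight-normalized cross-entropy gradient w.r.t. logits
  mat p = logits;
  softmax_rows_inplace(p);
  vec w(B);
  mat dlogits = p;
  double sumw = 0.0;
  for (int b = 0; b < B; ++b) {
    w[b] = cw_[yidx_[b] - 1];
    sumw += w[b];
    dlogits(b, yidx_[b] - 1) -= 1.0;
  }
  dlogits.each_col() %= (w / sumw);

  List grads;
  grads["Wc"] = pd.t() * dlogits;
  grads["bc"] = arma::sum(dlogits, 0);
  mat dpd = dlogits * Wc.t();
  if (use_dropout) dpd %= as<mat>(dmask_);

  mat dY(N, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int nr = nreal_[b];
    rowvec contrib = dpd.row(b) / (double)nr;
    for (int t = 0; t < nr; ++t) dY.row(b * T + t) = contrib;
  }
  rowvec dg, db;
  mat dX = ln_bwd(dY, lnf, lnfg, dg, db);
  grads["lnfg"] = dg;
  grads["lnfb"] = db;

  for (int l = n_layers - 1; l >= 0; --l) {
    LayerCache& cc = caches[l];
    // feed-forward sublayer
    const mat& dFF = dX;
    mat dG = dFF * W2[l].t();
    grads[lname(l, "W2")] = cc.G.t() * dFF;
    grads[lname(l, "b2")] = arma::sum(dFF, 0);
    mat dH1 = dG % gelu_grad(cc.H1);
    grads[lname(l, "W1")] = cc.M.t() * dH1;
    grads[lname(l, "b1")] = arma::sum(dH1, 0);
    mat dM = dH1 * W1[l].t();
    mat dX1 = ln_bwd(dM, cc.ln2, ln2g[l], dg, db);
    grads[lname(l, "ln2g")] = dg;
    grads[lname(l, "ln2b")] = db;
    dX1 += dX;
    // attention sublayer
    const mat& dAO = dX1;
    mat dO = dAO * Wo[l].t();
    grads[lname(l, "Wo")] = cc.O.t() * dAO;
    grads[lname(l, "bo")] = arma::sum(dAO, 0);
    mat dQ(N, d, arma::fill::zeros), dK(N, d, arma::fill::zeros),
        dV(N, d, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      const int nr = nreal_[b];
      const int r0 = b * T;
      for (int h = 0; h < n_heads; ++h) {
        const int c0 = h * dh;
        const mat& Pw = cc.attn[b][h];
        mat dOh = dO.submat(r0, c0, r0 + nr - 1, c0 + dh - 1);
        mat Vh = cc.V.submat(r0, c0, r0 + nr - 1, c0 + dh - 1);
        mat dP = dOh * Vh.t();
        dV.submat(r0, c0, r0 + nr - 1, c0 + dh - 1) = Pw.t() * dOh;
        vec rs = arma::sum(dP % Pw, 1);
        mat dS = Pw % (dP.each_col() - rs);
        dQ.submat(r0, c0, r0 + nr - 1, c0 + dh - 1) =
            dS * cc.K.submat(r0, c0, r0 + nr - 1, c0 + dh - 1) * scale;
        dK.submat(r0, c0, r0 + nr - 1, c0 + dh - 1) =
            dS.t() * cc.Q.submat(r0, c0, r0 + nr - 1, c0 + dh - 1) * scale;
      }
    }
    grads[lname(l, "Wq")] = cc.A.t() * dQ;
    grads[lname(l, "bq")] = arma::sum(dQ, 0);
    grads[lname(l, "Wk")] = cc.A.t() * dK;
    grads[lname(l, "bk")] = arma::sum(dK, 0);
    grads[lname(l, "Wv")] = cc.A.t() * dV;
    grads[lname(l, "bv")] = arma::sum(dV, 0);
    mat dA = dQ * Wq[l].t() + dK * Wk[l].t() + dV * Wv[l].t();
    mat dXl = ln_bwd(dA, cc.ln1, ln1g[l], dg, db);
    grads[lname(l, "ln1g")] = dg;
    grads[lname(l, "ln1b")] = db;
    dX = dX1 + dXl;
  }

  mat demb(emb.n_rows, d, arma::fill::zeros);
  mat dpos(pos.n_rows, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) {
      demb.row(flat_ids[b * T + t]) += dX.row(b * T + t);
      dpos.row(t) += dX.row(b * T + t);
    }
  grads["emb"] = demb;
  grads["pos"] = dpos;

  return List::create(Named("logits") = logits, Named("grads") = grads);
}
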