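// Batched forward / forward+backward passes of the MLP-Mixer regressor.
// Mirrors the reference R implementation (mixer_fwd / mixer_bwd) exactly;
// the R path is kept and cross-checked in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// GELU, sigmoid form: x * sigmoid(1.702 x)
static inline mat gelu_sig(const mat& x) { return 1.0 / (1.0 + exp(-1.702 * x)); }
static inline mat gelu_grad_s(const mat& x, const mat& s) {
  return s % (1.0 + 1.702 * x % (1.0 - s));
}

static inline mat add_bias(mat a, const rowvec& b) {
  a.each_row() += b;
  return a;
}

// (n_p*B) x C  ->  (C*B) x n_p, rows ordered channel-fastest then sample
static mat to_tokens(const mat& E, int n_p, int B, int C) {
  mat T(C * B, n_p);
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < B; ++b)
      for (int p = 0; p < n_p; ++p)
        T(c + b * C, p) = E(p + b * n_p, c);
  return T;
}

static mat from_tokens(const mat& T, int n_p, int B, int C) {
  mat E(n_p * B, C);
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < B; ++b)
      for (int p = 0; p < n_p; ++p)
        E(p + b * n_p, c) = T(c + b * C, p);
  return E;
}

struct LnCache { mat xhat; vec inv; };

static mat ln_fwd(const mat& x, const rowvec& g, const rowvec& b,
                  LnCache& cache) {
  const double eps = 1e-6;
  vec mu = mean(x, 1);
  mat xc = x.each_col() - mu;
  vec inv = 1.0 / sqrt(mean(xc % xc, 1) + eps);
  mat xhat = xc.each_col() % inv;
  cache.xhat = xhat; cache.inv = inv;
  mat out = xhat.each_row() % g;
  out.each_row() += b;
  return out;
}

static mat ln_bwd(const mat& dy, const LnCache& cache, const rowvec& g,
                  rowvec& dg, rowvec& db) {
  dg = sum(dy % cache.xhat, 0);
  db = sum(dy, 0);
  mat dxh = dy.each_row() % g;
  vec m1 = mean(dxh, 1);
  vec m2 = mean(dxh % cache.xhat, 1);
  mat dx = dxh.each_col() - m1;
  dx -= cache.xhat.each_col() % m2;
  return dx.each_col() % cache.inv;
}

static mat drop_mask(int nr, int nc, double rate) {
  mat m(nr, nc);
  double keep = 1.0 - rate;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      m(i, j) = (unif_rand() >= rate) ? 1.0 / keep : 0.0;
  return m;
}

struct BlockParams {
  rowvec ln1_g, ln1_b, ln2_g, ln2_b;
  mat tok1W, tok2W, ch1W, ch2W;
  rowvec tok1b, tok2b, ch1b, ch2b;
};

struct BlockCache {
  mat E, Tm, pre1, s1, m1, H1d, E1, V, pre2, s2, m2, H2d;
  LnCache ln1, ln2;
  bool dropped;
};

static BlockParams get_block(const Rcpp::List& pr, int bi) {
  Rcpp::List bp = pr[std::string("block") + std::to_string(bi + 1)];
  BlockParams p;
  p.ln1_g = Rcpp::as<rowvec>(bp["ln1_g"]);
  p.ln1_b = Rcpp::as<rowvec>(bp["ln1_b"]);
  p.ln2_g = Rcpp::as<rowvec>(bp["ln2_g"]);
  p.ln2_b = Rcpp::as<rowvec>(bp["ln2_b"]);
  Rcpp::List tok1 = bp["tok1"], tok2 = bp["tok2"], ch1 = bp["ch1"], ch2 = bp["ch2"];
  p.tok1W = Rcpp::as<mat>(tok1["W"]); p.tok1b = Rcpp::as<rowvec>(tok1["b"]);
  p.tok2W = Rcpp::as<mat>(tok2["W"]); p.tok2b = Rcpp::as<rowvec>(tok2["b"]);
  p.ch1W = Rcpp::as<mat>(ch1["W"]);  p.ch1b = Rcpp::as<rowvec>(ch1["b"]);
  p.ch2W = Rcpp::as<mat>(ch2["W"]);  p.ch2b = Rcpp::as<rowvec>(ch2["b"]);
  return p;
}

// Embed patches: x is B x padded_length, returns (n_p*B) x C.
static mat embed(const mat& x, const mat& We, const rowvec& be,
                 int P, int n_p, mat& Pm) {
  int B = x.n_rows;
  Pm.set_size(P, n_p * B);
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < n_p; ++p)
      for (int i = 0; i < P; ++i)
        Pm(i, p + b * n_p) = x(b, p * P + i);
  return add_bias(Pm.t() * We, be);
}

// Shared forward; caches filled only when `train_caches` is non-null.
static vec forward_core(const Rcpp::List& pr, const mat& x, int P, int n_p,
                        int C, int n_blocks, double drop_rate,
                        std::vector<BlockCache>* caches,
                        std::vector<mat>* head_in, std::vector<mat>* head_pre,
                        std::vector<mat>* head_s, mat* Pm_out, mat* Fm_out) {
  int B = x.n_rows;
  Rcpp::List emb = pr["embed"];
  mat Pm;
  mat E = embed(x, Rcpp::as<mat>(emb["W"]), Rcpp::as<rowvec>(emb["b"]),
                P, n_p, Pm);
  if (Pm_out) *Pm_out = Pm;
  for (int bi = 0; bi < n_blocks; ++bi) {
    BlockParams bp = get_block(pr, bi);
    BlockCache bc;
    mat U = ln_fwd(E, bp.ln1_g, bp.ln1_b, bc.ln1);
    mat Tm = to_tokens(U, n_p, B, C);
    mat pre1 = add_bias(Tm * bp.tok1W, bp.tok1b);
    mat s1 = gelu_sig(pre1);
    mat H1 = pre1 % s1;
    bc.dropped = drop_rate > 0;
    if (bc.dropped) { bc.m1 = drop_mask(H1.n_rows, H1.n_cols, drop_rate); H1 %= bc.m1; }
    mat O1 = add_bias(H1 * bp.tok2W, bp.tok2b);
    mat E1 = E + from_tokens(O1, n_p, B, C);
    mat V = ln_fwd(E1, bp.ln2_g, bp.ln2_b, bc.ln2);
    mat pre2 = add_bias(V * bp.ch1W, bp.ch1b);
    mat s2 = gelu_sig(pre2);
    mat H2 = pre2 % s2;
    if (bc.dropped) { bc.m2 = drop_mask(H2.n_rows, H2.n_cols, drop_rate); H2 %= bc.m2; }
    mat E2 = E1 + add_bias(H2 * bp.ch2W, bp.ch2b);
    if (caches) {
      bc.E = E; bc.Tm = Tm; bc.pre1 = pre1; bc.s1 = s1; bc.H1d = H1;
      bc.E1 = E1; bc.V = V; bc.pre2 = pre2; bc.s2 = s2; bc.H2d = H2;
      (*caches)[bi] = bc;
    }
    E = E2;
  }
  // flatten: B x (n_p*C), per sample patch-fastest within channel
  mat Fm(B, n_p * C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < n_p; ++p)
        Fm(b, p + c * n_p) = E(p + b * n_p, c);
  if (Fm_out) *Fm_out = Fm;
  Rcpp::List head = pr["head"];
  int n_head = head.size();
  mat a = Fm;
  for (int i = 0; i < n_head; ++i) {
    Rcpp::List li = head[i];
    mat pre = add_bias(a * Rcpp::as<mat>(li["W"]), Rcpp::as<rowvec>(li["b"]));
    if (head_in) (*head_in)[i] = a;
    if (head_pre) (*head_pre)[i] = pre;
    if (i < n_head - 1) {
      mat s = gelu_sig(pre);
      if (head_s) (*head_s)[i] = s;
      a = pre % s;
    } else a = pre;
  }
  return vec(a.col(0));
}

// [[Rcpp::export(name = ".mixer_infer_cpp")]]
Rcpp::NumericVector mixer_infer_cpp(Rcpp::List params, arma::mat x,
                                    int patch_size, int n_patches,
                                    int channel_dim, int n_blocks) {
  vec y = forward_core(params, x, patch_size, n_patches, channel_dim,
                       n_blocks, 0.0, nullptr, nullptr, nullptr, nullptr,
                       nullptr, nullptr);
  return Rcpp::wrap(y);
}

// Forward + backward of the batch MSE for one minibatch: returns
// list(y, grads) with grads mirroring the parameter list structure.
// [[Rcpp::export(name = ".mixer_step_cpp")]]
Rcpp::List mixer_step_cpp(Rcpp::List params, arma::mat x, arma::vec yb,
                          int patch_size, int n_patches, int channel_dim,
                          int n_blocks, double drop_rate) {
  int B = x.n_rows, n_p = n_patches, C = channel_dim;
  std::vector<BlockCache> caches(n_blocks);
  Rcpp::List head = params["head"];
  int n_head = head.size();
  std::vector<mat> head_in(n_head), head_pre(n_head), head_s(n_head);
  mat Pm, Fm;
  vec y = forward_core(params, x, patch_size, n_p, C, n_blocks, drop_rate,
                       &caches, &head_in, &head_pre, &head_s, &Pm, &Fm);
  vec dy = 2.0 * (y - yb) / (double) y.n_elem;
  Rcpp::List grads;
  // head backward
  mat da = mat(dy);
  Rcpp::List ghead(n_head);
  for (int i = n_head - 1; i >= 0; --i) {
    Rcpp::List li = head[i];
    mat dpre = (i < n_head - 1) ? mat(da % gelu_grad_s(head_pre[i], head_s[i]))
                                : da;
    ghead[i] = Rcpp::List::create(
      Rcpp::Named("W") = mat(head_in[i].t() * dpre),
      Rcpp::Named("b") = rowvec(sum(dpre, 0)));
    da = dpre * Rcpp::as<mat>(li["W"]).t();
  }
  ghead.attr("names") = head.attr("names");
  // un-flatten
  mat dE(n_p * B, C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < n_p; ++p)
        dE(p + b * n_p, c) = da(b, p + c * n_p);
  for (int bi = n_blocks - 1; bi >= 0; --bi) {
    BlockParams bp = get_block(params, bi);
    BlockCache& bc = caches[bi];
    // channel mixing
    mat dO2 = dE;
    mat gch2W = bc.H2d.t() * dO2;
    rowvec gch2b = sum(dO2, 0);
    mat dH2 = dO2 * bp.ch2W.t();
    if (bc.dropped) dH2 %= bc.m2;
    mat dpre2 = dH2 % gelu_grad_s(bc.pre2, bc.s2);
    mat gch1W = bc.V.t() * dpre2;
    rowvec gch1b = sum(dpre2, 0);
    mat dV = dpre2 * bp.ch1W.t();
    rowvec gln2g, gln2b;
    mat dE1 = dE + ln_bwd(dV, bc.ln2, bp.ln2_g, gln2g, gln2b);
    // token mixing
    mat dO1 = to_tokens(dE1, n_p, B, C);
    mat gtok2W = bc.H1d.t() * dO1;
    rowvec gtok2b = sum(dO1, 0);
    mat dH1 = dO1 * bp.tok2W.t();
    if (bc.dropped) dH1 %= bc.m1;
    mat dpre1 = dH1 % gelu_grad_s(bc.pre1, bc.s1);
    mat gtok1W = bc.Tm.t() * dpre1;
    rowvec gtok1b = sum(dpre1, 0);
    mat dTm = dpre1 * bp.tok1W.t();
    mat dU = from_tokens(dTm, n_p, B, C);
    rowvec gln1g, gln1b;
    dE = dE1 + ln_bwd(dU, bc.ln1, bp.ln1_g, gln1g, gln1b);
    grads[std::string("block") + std::to_string(bi + 1)] = Rcpp::List::create(
      Rcpp::Named("ln1_g") = gln1g, Rcpp::Named("ln1_b") = gln1b,
      Rcpp::Named("tok1") = Rcpp::List::create(Rcpp::Named("W") = gtok1W,
                                               Rcpp::Named("b") = gtok1b),
      Rcpp::Named("tok2") = Rcpp::List::create(Rcpp::Named("W") = gtok2W,
                                               Rcpp::Named("b") = gtok2b),
      Rcpp::Named("ln2_g") = gln2g, Rcpp::Named("ln2_b") = gln2b,
      Rcpp::Named("ch1") = Rcpp::List::create(Rcpp::Named("W") = gch1W,
                                              Rcpp::Named("b") = gch1b),
      Rcpp::Named("ch2") = Rcpp::List::create(Rcpp::Named("W") = gch2W,
                                              Rcpp::Named("b") = gch2b));
  }
  grads["embed"] = Rcpp::List::create(Rcpp::Named("W") = mat(Pm * dE),
                                      Rcpp::Named("b") = rowvec(sum(dE, 0)));
  grads["head"] = ghead;
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("grads") = grads);
}
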