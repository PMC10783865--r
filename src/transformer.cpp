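// Transformer encoder core: forward pass, attention extraction and full
// backpropagation for the masked-language-model (MLM) and binding-score
// regression (NSP) heads. Sequences are stacked by true length, so padding
// positions never enter the computation graph: pad invariance is exact.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::cube;
using arma::uword;

static const double LN_EPS = 1e-5;

struct EncParams {
  mat tok, pos, seg;
  rowvec emb_g, emb_b;
  std::vector<mat> Wq, Wk, Wv, Wo, W1, W2;
  std::vector<rowvec> bq, bk, bv, bo, b1f, b2f, g1, be1, g2, be2;
  mat mlmW;
  rowvec mlmb;
  mat nspW1;
  rowvec nspb1;
  vec nspw;
  double nspb;
  int nL, nH, D, F, V, max_len;
  bool has_seg, has_nsp;
};

static mat getm(const List& p, const std::string& nm) {
  return as<mat>(p[nm]);
}
static rowvec getr(const List& p, const std::string& nm) {
  return as<rowvec>(p[nm]);
}

static EncParams parse_params(const List& p, int n_layers, int n_heads,
                              bool use_seg, bool use_nsp) {
  EncParams e;
  e.nL = n_layers; e.nH = n_heads;
  e.tok = getm(p, "tok_emb");
  e.pos = getm(p, "pos_emb");
  e.D = e.tok.n_cols;
  e.V = e.tok.n_rows;
  e.max_len = e.pos.n_rows;
  e.has_seg = use_seg;
  if (use_seg) e.seg = getm(p, "seg_emb");
  e.emb_g = getr(p, "emb_ln_g");
  e.emb_b = getr(p, "emb_ln_b");
  char buf[64];
  for (int l = 1; l <= n_layers; ++l) {
    #define GETL(field, suffix, fn) \
      snprintf(buf, sizeof(buf), "l%d_" suffix, l); e.field.push_back(fn(p, buf));
    GETL(Wq, "Wq", getm) GETL(bq, "bq", getr)
    GETL(Wk, "Wk", getm) GETL(bk, "bk", getr)
    GETL(Wv, "Wv", getm) GETL(bv, "bv", getr)
    GETL(Wo, "Wo", getm) GETL(bo, "bo", getr)
    GETL(g1, "ln1_g", getr) GETL(be1, "ln1_b", getr)
    GETL(W1, "W1", getm)  GETL(b1f, "b1", getr)
    GETL(W2, "W2", getm)  GETL(b2f, "b2", getr)
    GETL(g2, "ln2_g", getr) GETL(be2, "ln2_b", getr)
    #undef GETL
  }
  e.F = e.W1[0].n_cols;
  e.mlmW = getm(p, "mlm_W");
  e.mlmb = getr(p, "mlm_b");
  e.has_nsp = use_nsp;
  if (use_nsp) {
    e.nspW1 = getm(p, "nsp_W1");
    e.nspb1 = getr(p, "nsp_b1");
    e.nspw = as<vec>(p["nsp_w"]);
    e.nspb = as<double>(p["nsp_b"]);
  }
  return e;
}

// --- layer norm -------------------------------------------------------------

static mat ln_fwd(const mat& X, const rowvec& g, const rowvec& b,
                  mat& xhat, vec& inv_sd) {
  vec mu = arma::mean(X, 1);
  xhat = X.each_col() - mu;
  inv_sd = 1.0 / arma::sqrt(arma::mean(arma::square(xhat), 1) + LN_EPS);
  xhat.each_col() %= inv_sd;
  mat Y = xhat.each_row() % g;
  Y.each_row() += b;
  return Y;
}

static mat ln_bwd(const mat& dY, const mat& xhat, const vec& inv_sd,
                  const rowvec& g, rowvec& dg, rowvec& db) {
  dg += arma::sum(dY % xhat, 0);
  db += arma::sum(dY, 0);
  mat y = dY.each_row() % g;
  vec m1 = arma::mean(y, 1);
  vec m2 = arma::mean(y % xhat, 1);
  mat dX = y.each_col() - m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= inv_sd;
  return dX;
}

// --- GELU (exact, erf form) -------------------------------------------------

static const double INV_SQRT2 = 0.7071067811865475244;
static const double INV_SQRT2PI = 0.3989422804014326779;

static mat gelu(const mat& X) {
  mat Y = X;
  Y.transform([](double x) { return 0.5 * x * (1.0 + std::erf(x * INV_SQRT2)); });
  return Y;
}
static mat dgelu(const mat& X) {
  mat Y = X;
  Y.transform([](double x) {
    double cdf = 0.5 * (1.0 + std::erf(x * INV_SQRT2));
    double pdf = INV_SQRT2PI * std::exp(-0.5 * x * x);
    return cdf + x * pdf;
  });
  return Y;
}

// --- caches -----------------------------------------------------------------

struct LayerCache {
  mat Xin, Q, K, V, C, Xa, Hpre, Hact;
  mat drop1, drop2;        // inverted-dropout scale masks; empty when unused
  mat xhat1, xhat2;
  vec inv1, inv2;
  std::vector<cube> attn;  // per sequence: T x T x H
};

struct FwdCache {
  mat xhat0; vec inv0;
  std::vector<LayerCache> layers;
  mat X;  // final hidden states, stacked
};

static mat rand_dropmask(uword n, uword m, double p) {
  mat M(n, m);
  const double scale = 1.0 / (1.0 - p);
  for (uword j = 0; j < m; ++j)
    for (uword i = 0; i < n; ++i)
      M(i, j) = (R::unif_rand() < p) ? 0.0 : scale;
  return M;
}

// Stacked forward. offs[b]..offs[b]+T[b]-1 are the rows of sequence b.
static void forward_stacked(const EncParams& e, const arma::ivec& idsS,
                            const arma::ivec& posS, const arma::ivec& segS,
                            const std::vector<uword>& offs,
                            const std::vector<uword>& Ts,
                            double dropout, bool training, bool keep_cache,
                            FwdCache& fc) {
  const uword N = idsS.n_elem;
  const int dh = e.D / e.nH;
  const double sc = 1.0 / std::sqrt((double)dh);
  const bool drop = training && dropout > 0.0;
  const uword B = offs.size();

  mat E = e.tok.rows(arma::conv_to<arma::uvec>::from(idsS));
  E += e.pos.rows(arma::conv_to<arma::uvec>::from(posS));
  if (e.has_seg) E += e.seg.rows(arma::conv_to<arma::uvec>::from(segS));
  mat X = ln_fwd(E, e.emb_g, e.emb_b, fc.xhat0, fc.inv0);

  fc.layers.resize(e.nL);
  for (int l = 0; l < e.nL; ++l) {
    LayerCache& lc = fc.layers[l];
    if (keep_cache) lc.Xin = X;
    mat Q = X * e.Wq[l]; Q.each_row() += e.bq[l];
    mat K = X * e.Wk[l]; K.each_row() += e.bk[l];
    mat V = X * e.Wv[l]; V.each_row() += e.bv[l];
    mat C(N, e.D);
    lc.attn.resize(B);
    for (uword b = 0; b < B; ++b) {
      arma::span rs(offs[b], offs[b] + Ts[b] - 1);
      cube& Ab = lc.attn[b];
      Ab.set_size(Ts[b], Ts[b], e.nH);
      for (int h = 0; h < e.nH; ++h) {
        arma::span cs(h * dh, (h + 1) * dh - 1);
        mat S = Q(rs, cs) * K(rs, cs).t() * sc;
        // row-wise softmax, vectorized
        S.each_col() -= arma::max(S, 1);
        S = arma::exp(S);
        S.each_col() /= arma::sum(S, 1);
        Ab.slice(h) = S;
        C(rs, cs) = S * V(rs, cs);
      }
    }
    mat O = C * e.Wo[l]; O.each_row() += e.bo[l];
    if (drop) { lc.drop1 = rand_dropmask(N, e.D, dropout); O %= lc.drop1; }
    mat Xa = ln_fwd(X + O, e.g1[l], e.be1[l], lc.xhat1, lc.inv1);
    mat Hpre = Xa * e.W1[l]; Hpre.each_row() += e.b1f[l];
    mat Hact = gelu(Hpre);
    mat F2 = Hact * e.W2[l]; F2.each_row() += e.b2f[l];
    if (drop) { lc.drop2 = rand_dropmask(N, e.D, dropout); F2 %= lc.drop2; }
    mat Xn = ln_fwd(Xa + F2, e.g2[l], e.be2[l], lc.xhat2, lc.inv2);
    if (keep_cache) {
      lc.Q = std::move(Q); lc.K = std::move(K); lc.V = std::move(V);
      lc.C = std::move(C); lc.Xa = std::move(Xa);
      lc.Hpre = std::move(Hpre); lc.Hact = std::move(Hact);
    } else if (l + 1 < e.nL) {
      lc.attn.shrink_to_fit();
    }
    X = std::move(Xn);
  }
  fc.X = std::move(X);
}

static void stack_inputs(const IntegerMatrix& ids, const IntegerMatrix& segs,
                         const IntegerVector& lens, bool use_seg,
                         arma::ivec& idsS, arma::ivec& posS, arma::ivec& segS,
                         std::vector<uword>& offs, std::vector<uword>& Ts) {
  const int B = ids.nrow();
  uword N = 0;
  for (int b = 0; b < B; ++b) N += (uword)lens[b];
  idsS.set_size(N); posS.set_size(N); segS.set_size(N);
  offs.resize(B); Ts.resize(B);
  uword r = 0;
  for (int b = 0; b < B; ++b) {
    offs[b] = r; Ts[b] = (uword)lens[b];
    for (int t = 0; t < lens[b]; ++t, ++r) {
      idsS(r) = ids(b, t);
      posS(r) = t;
      segS(r) = use_seg ? segs(b, t) : 0;
    }
  }
}

// [[Rcpp::export]]
List cpp_encode(List params, IntegerMatrix ids, IntegerMatrix segs,
                IntegerVector lens, int n_layers, int n_heads, bool use_seg,
                bool return_attention) {
  EncParams e = parse_params(params, n_layers, n_heads, use_seg, false);
  arma::ivec idsS, posS, segS;
  std::vector<uword> offs, Ts;
  stack_inputs(ids, segs, lens, use_seg, idsS, posS, segS, offs, Ts);
  FwdCache fc;
  forward_stacked(e, idsS, posS, segS, offs, Ts, 0.0, false,
                  return_attention, fc);
  const int B = ids.nrow();
  cube H(e.max_len, e.D, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    H.slice(b).rows(0, Ts[b] - 1) =
        fc.X.rows(offs[b], offs[b] + Ts[b] - 1);
  List out = List::create(Named("hidden") = H);
  if (return_attention) {
    // received attention: column sums of each attention matrix,
    // one column per (layer, head), zero at pad positions
    cube A(e.max_len, e.nL * e.nH, B, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      for (int l = 0; l < e.nL; ++l)
        for (int h = 0; h < e.nH; ++h) {
          rowvec cs = arma::sum(fc.layers[l].attn[b].slice(h), 0);
          A.slice(b).col(l * e.nH + h).rows(0, Ts[b] - 1) = cs.t();
        }
    out["attn_received"] = A;
  }
  return out;
}

struct Grads {
  mat tok, pos, seg;
  rowvec emb_g, emb_b;
  std::vector<mat> Wq, Wk, Wv, Wo, W1, W2;
  std::vector<rowvec> bq, bk, bv, bo, b1f, b2f, g1, be1, g2, be2;
  mat mlmW; rowvec mlmb;
  mat nspW1; rowvec nspb1;
  vec nspw; double nspb;
};

static void zeros_like(const EncParams& e, Grads& g) {
  g.tok.zeros(e.tok.n_rows, e.tok.n_cols);
  g.pos.zeros(e.pos.n_rows, e.pos.n_cols);
  if (e.has_seg) g.seg.zeros(e.seg.n_rows, e.seg.n_cols);
  g.emb_g.zeros(e.D); g.emb_b.zeros(e.D);
  for (int l = 0; l < e.nL; ++l) {
    g.Wq.push_back(mat(e.D, e.D, arma::fill::zeros));
    g.Wk.push_back(mat(e.D, e.D, arma::fill::zeros));
    g.Wv.push_back(mat(e.D, e.D, arma::fill::zeros));
    g.Wo.push_back(mat(e.D, e.D, arma::fill::zeros));
    g.W1.push_back(mat(e.D, e.F, arma::fill::zeros));
    g.W2.push_back(mat(e.F, e.D, arma::fill::zeros));
    g.bq.push_back(rowvec(e.D, arma::fill::zeros));
    g.bk.push_back(rowvec(e.D, arma::fill::zeros));
    g.bv.push_back(rowvec(e.D, arma::fill::zeros));
    g.bo.push_back(rowvec(e.D, arma::fill::zeros));
    g.b1f.push_back(rowvec(e.F, arma::fill::zeros));
    g.b2f.push_back(rowvec(e.D, arma::fill::zeros));
    g.g1.push_back(rowvec(e.D, arma::fill::zeros));
    g.be1.push_back(rowvec(e.D, arma::fill::zeros));
    g.g2.push_back(rowvec(e.D, arma::fill::zeros));
    g.be2.push_back(rowvec(e.D, arma::fill::zeros));
  }
  g.mlmW.zeros(e.mlmW.n_rows, e.mlmW.n_cols);
  g.mlmb.zeros(e.mlmb.n_elem);
  if (e.has_nsp) {
    g.nspW1.zeros(e.nspW1.n_rows, e.nspW1.n_cols);
    g.nspb1.zeros(e.nspb1.n_elem);
    g.nspw.zeros(e.nspw.n_elem);
    g.nspb = 0.0;
  }
}

static List grads_to_list(const EncParams& e, const Grads& g) {
  List out;
  out["tok_emb"] = g.tok;
  out["pos_emb"] = g.pos;
  if (e.has_seg) out["seg_emb"] = g.seg;
  out["emb_ln_g"] = g.emb_g; out["emb_ln_b"] = g.emb_b;
  char buf[64];
  for (int l = 0; l < e.nL; ++l) {
    #define PUTL(field, suffix) \
      snprintf(buf, sizeof(buf), "l%d_" suffix, l + 1); out[buf] = g.field[l];
    PUTL(Wq, "Wq") PUTL(bq, "bq") PUTL(Wk, "Wk") PUTL(bk, "bk")
    PUTL(Wv, "Wv") PUTL(bv, "bv") PUTL(Wo, "Wo") PUTL(bo, "bo")
    PUTL(g1, "ln1_g") PUTL(be1, "ln1_b")
    PUTL(W1, "W1") PUTL(b1f, "b1") PUTL(W2, "W2") PUTL(b2f, "b2")
    PUTL(g2, "ln2_g") PUTL(be2, "ln2_b")
    #undef PUTL
  }
  out["mlm_W"] = g.mlmW; out["mlm_b"] = g.mlmb;
  if (e.has_nsp) {
    out["nsp_W1"] = g.nspW1; out["nsp_b1"] = g.nspb1;
    out["nsp_w"] = g.nspw; out["nsp_b"] = g.nspb;
  }
  return out;
}

// Joint MLM + NSP loss and gradients over a batch.
// targets: 0-based token id at masked positions, -1 elsewhere.
// labels: regression target per sequence, NaN to skip the NSP head.
// [[Rcpp::export]]
List cpp_bert_grad(List params, IntegerMatrix ids, IntegerMatrix targets,
                   IntegerMatrix segs, IntegerVector lens, NumericVector labels,
                   int n_layers, int n_heads, bool use_seg, bool use_nsp,
                   double dropout, bool training, bool want_grads) {
  EncParams e = parse_params(params, n_layers, n_heads, use_seg, use_nsp);
  arma::ivec idsS, posS, segS;
  std::vector<uword> offs, Ts;
  stack_inputs(ids, segs, lens, use_seg, idsS, posS, segS, offs, Ts);
  const uword N = idsS.n_elem;
  const int B = ids.nrow();
  const int dh = e.D / e.nH;
  const double sc = 1.0 / std::sqrt((double)dh);
  const bool drop = training && dropout > 0.0;

  FwdCache fc;
  forward_stacked(e, idsS, posS, segS, offs, Ts, dropout, training, true, fc);

  // collect masked positions (stacked row index + target id)
  std::vector<uword> mrow;
  std::vector<int> mtgt;
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < lens[b]; ++t)
      if (targets(b, t) >= 0) {
        mrow.push_back(offs[b] + (uword)t);
        mtgt.push_back(targets(b, t));
      }
  const uword M = mrow.size();

  double ce = 0.0, mse = 0.0;
  mat dX(N, e.D, arma::fill::zeros);
  Grads g;
  if (want_grads) zeros_like(e, g);

  if (M > 0) {
    mat Xm(M, e.D);
    for (uword k = 0; k < M; ++k) Xm.row(k) = fc.X.row(mrow[k]);
    mat Lg = Xm * e.mlmW; Lg.each_row() += e.mlmb;
    for (uword k = 0; k < M; ++k) {
      rowvec r = Lg.row(k);
      double mx = r.max();
      rowvec ex = arma::exp(r - mx);
      double Z = arma::accu(ex);
      ce += -(r(mtgt[k]) - mx - std::log(Z));
      if (want_grads) {
        rowvec p = ex / Z;
        p(mtgt[k]) -= 1.0;
        p /= (double)M;
        Lg.row(k) = p;  // reuse as dlogits
      }
    }
    ce /= (double)M;
    if (want_grads) {
      g.mlmW += Xm.t() * Lg;
      g.mlmb += arma::sum(Lg, 0);
      mat dXm = Lg * e.mlmW.t();
      for (uword k = 0; k < M; ++k) dX.row(mrow[k]) += dXm.row(k);
    }
  }

  int nlab = 0;
  if (use_nsp) {
    for (int b = 0; b < B; ++b) if (!NumericVector::is_na(labels[b])) ++nlab;
    if (nlab > 0) {
      for (int b = 0; b < B; ++b) {
        if (NumericVector::is_na(labels[b])) continue;
        // pooled representation: [whole complex, epitope segment], each a
        // sum over positions scaled by 1/sqrt(count) so per-dimension
        // variance is length-independent; a one-hidden-layer MLP maps it
        // to a logistic binding score
        arma::span rs(offs[b], offs[b] + Ts[b] - 1);
        const double ps = 1.0 / std::sqrt((double)Ts[b]);
        arma::uvec epi(Ts[b]);
        uword ne = 0;
        for (uword t = 0; t < Ts[b]; ++t)
          if (segS(offs[b] + t) == 1) epi(ne++) = offs[b] + t;
        epi.resize(ne);
        const double pe = ne > 0 ? 1.0 / std::sqrt((double)ne) : 0.0;
        rowvec pooled(2 * e.D);
        pooled.cols(0, e.D - 1) = arma::sum(fc.X.rows(rs), 0) * ps;
        pooled.cols(e.D, 2 * e.D - 1) =
            ne > 0 ? rowvec(arma::sum(fc.X.rows(epi), 0) * pe)
                   : rowvec(e.D, arma::fill::zeros);
        rowvec hpre = pooled * e.nspW1 + e.nspb1;
        rowvec h = arma::clamp(hpre, 0.0, arma::datum::inf);
        double z = arma::dot(h, e.nspw.t()) + e.nspb;
        double pbd = 1.0 / (1.0 + std::exp(-z));
        double dlt = pbd - labels[b];
        mse += dlt * dlt;
        if (want_grads) {
          double dz = 2.0 * dlt * pbd * (1.0 - pbd) / (double)nlab;
          g.nspw += h.t() * dz;
          g.nspb += dz;
          rowvec dh = dz * e.nspw.t();
          rowvec dhpre = dh % arma::conv_to<rowvec>::from(hpre > 0);
          g.nspW1 += pooled.t() * dhpre;
          g.nspb1 += dhpre;
          rowvec dpooled = dhpre * e.nspW1.t();
          dX.rows(rs) += arma::ones<vec>(Ts[b]) *
                         (dpooled.cols(0, e.D - 1) * ps);
          if (ne > 0)
            dX.rows(epi) += arma::ones<vec>(ne) *
                            (dpooled.cols(e.D, 2 * e.D - 1) * pe);
        }
      }
      mse /= (double)nlab;
    }
  }

  if (want_grads) {
    for (int l = e.nL - 1; l >= 0; --l) {
      LayerCache& lc = fc.layers[l];
      mat dR2 = ln_bwd(dX, lc.xhat2, lc.inv2, e.g2[l], g.g2[l], g.be2[l]);
      mat dXa = dR2;
      mat dF2 = drop ? mat(dR2 % lc.drop2) : dR2;
      mat dH = dF2 * e.W2[l].t();
      g.W2[l] += lc.Hact.t() * dF2;
      g.b2f[l] += arma::sum(dF2, 0);
      mat dHpre = dH % dgelu(lc.Hpre);
      g.W1[l] += lc.Xa.t() * dHpre;
      g.b1f[l] += arma::sum(dHpre, 0);
      dXa += dHpre * e.W1[l].t();
      mat dR1 = ln_bwd(dXa, lc.xhat1, lc.inv1, e.g1[l], g.g1[l], g.be1[l]);
      mat dXin = dR1;
      mat dO = drop ? mat(dR1 % lc.drop1) : dR1;
      mat dC = dO * e.Wo[l].t();
      g.Wo[l] += lc.C.t() * dO;
      g.bo[l] += arma::sum(dO, 0);
      mat dQ(N, e.D, arma::fill::zeros), dK(N, e.D, arma::fill::zeros),
          dV(N, e.D, arma::fill::zeros);
      for (int b = 0; b < B; ++b) {
        arma::span rs(offs[b], offs[b] + Ts[b] - 1);
        for (int h = 0; h < e.nH; ++h) {
          arma::span csp(h * dh, (h + 1) * dh - 1);
          const mat& Ab = lc.attn[b].slice(h);
          mat dOh = dC(rs, csp);
          mat Vh = lc.V(rs, csp);
          mat dA = dOh * Vh.t();
          dV(rs, csp) += Ab.t() * dOh;
          mat tmp = dA % Ab;
          vec rsum = arma::sum(tmp, 1);
          mat dS = Ab % (dA.each_col() - rsum);
          dQ(rs, csp) += dS * lc.K(rs, csp) * sc;
          dK(rs, csp) += dS.t() * lc.Q(rs, csp) * sc;
        }
      }
      dXin += dQ * e.Wq[l].t() + dK * e.Wk[l].t() + dV * e.Wv[l].t();
      g.Wq[l] += lc.Xin.t() * dQ; g.bq[l] += arma::sum(dQ, 0);
      g.Wk[l] += lc.Xin.t() * dK; g.bk[l] += arma::sum(dK, 0);
      g.Wv[l] += lc.Xin.t() * dV; g.bv[l] += arma::sum(dV, 0);
      dX = std::move(dXin);
    }
    mat dE = ln_bwd(dX, fc.xhat0, fc.inv0, e.emb_g, g.emb_g, g.emb_b);
    for (uword r = 0; r < N; ++r) {
      g.tok.row(idsS(r)) += dE.row(r);
      g.pos.row(posS(r)) += dE.row(r);
      if (e.has_seg) g.seg.row(segS(r)) += dE.row(r);
    }
  }

  List out = List::create(Named("ce") = ce, Named("mse") = mse,
                          Named("n_masked") = (double)M,
                          Named("n_labeled") = (double)nlab);
  if (want_grads) out["grads"] = grads_to_list(e, g);
  return out;
}
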