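// Compact neural-network core for the two scorer families:
//  - "recurrent": per-sequence LSTM encoders over embedded residue indices,
//    final hidden states concatenated into a fully connected head.
//  - "convolutional": per-sequence 1-D convolutions over (implicit) one-hot
//    matrices, ReLU + global max pooling per filter size, concatenated into
//    the same style of head.
// Parameters live in one flat vector; the layout is defined here (and only
// here) so the R side derives offsets from nn_param_layout(). All arithmetic
// is deterministic and single-threaded.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int ALPHA = 20; // amino-acid alphabet size; index 0 is pad

struct PDef {
  std::string name;
  std::string group;
  int d1, d2;
  size_t offset; // 0-based into the flat parameter vector
};

static std::vector<PDef> build_layout(const List& cfg) {
  std::string family = as<std::string>(cfg["family"]);
  std::vector<PDef> defs;
  size_t off = 0;
  auto add = [&](const std::string& n, const std::string& g, int d1, int d2) {
    defs.push_back(PDef{n, g, d1, d2, off});
    off += (size_t)d1 * (size_t)d2;
  };
  int feat = 0;
  const char* sides[2] = {"cdr3", "pep"};
  if (family == "convolutional") {
    IntegerVector ks = cfg["conv_filter_sizes"];
    int C = as<int>(cfg["conv_channels"]);
    for (int s = 0; s < 2; ++s) {
      std::string g = (s == 0) ? "enc_cdr3" : "enc_pep";
      for (int i = 0; i < ks.size(); ++i) {
        int k = ks[i];
        add(std::string("conv_W_") + sides[s] + "_" + std::to_string(k), g, ALPHA * k, C);
        add(std::string("conv_b_") + sides[s] + "_" + std::to_string(k), g, 1, C);
      }
    }
    feat = 2 * ks.size() * C;
  } else if (family == "recurrent") {
    int E = as<int>(cfg["embed_dim"]);
    int H = as<int>(cfg["hidden_dim"]);
    for (int s = 0; s < 2; ++s) {
      std::string g = (s == 0) ? "enc_cdr3" : "enc_pep";
      add(std::string("emb_") + sides[s], g, ALPHA, E);
      add(std::string("lstm_Wx_") + sides[s], g, E, 4 * H);
      add(std::string("lstm_Wh_") + sides[s], g, H, 4 * H);
      add(std::string("lstm_b_") + sides[s], g, 1, 4 * H);
    }
    feat = 2 * H;
  } else {
    stop("unknown scorer family: %s", family.c_str());
  }
  IntegerVector hl = cfg["head_layers"];
  int prev = feat;
  for (int i = 0; i < hl.size(); ++i) {
    add("head_W" + std::to_string(i + 1), "head", prev, hl[i]);
    add("head_b" + std::to_string(i + 1), "head", 1, hl[i]);
    prev = hl[i];
  }
  add("head_Wout", "head", prev, 1);
  add("head_bout", "head", 1, 1);
  return defs;
}

// [[Rcpp::export]]
DataFrame nn_param_layout(List cfg) {
  std::vector<PDef> defs = build_layout(cfg);
  int n = defs.size();
  CharacterVector name(n), group(n);
  IntegerVector d1(n), d2(n);
  NumericVector offset(n), len(n);
  for (int i = 0; i < n; ++i) {
    name[i] = defs[i].name;
    group[i] = defs[i].group;
    d1[i] = defs[i].d1;
    d2[i] = defs[i].d2;
    offset[i] = (double)defs[i].offset + 1; // 1-based for R
    len[i] = (double)defs[i].d1 * defs[i].d2;
  }
  return DataFrame::create(_["name"] = name, _["group"] = group,
                           _["d1"] = d1, _["d2"] = d2,
                           _["offset"] = offset, _["length"] = len,
                           _["stringsAsFactors"] = false);
}

// Read-only / writable views into flat vectors, keyed by parameter name.
typedef std::map<std::string, arma::mat> MatMap;

static MatMap make_views(const std::vector<PDef>& defs, double* base) {
  MatMap m;
  for (const PDef& d : defs)
    m.emplace(d.name, arma::mat(base + d.offset, d.d1, d.d2, false, true));
  return m;
}

// ---------- convolutional encoder ----------

struct ConvCache {
  // per filter size: raw pooled max and argmax window start (or -1)
  std::vector<arma::mat> rawmax;          // each B x C
  std::vector<arma::Mat<int>> argmax;     // each B x C
};

static void conv_side_forward(const MatMap& P, const std::string& side,
                              const IntegerMatrix& X, const IntegerVector& len,
                              const IntegerVector& ks, int C,
                              arma::mat& feat, int featcol0, ConvCache& cache) {
  int B = X.nrow();
  cache.rawmax.clear();
  cache.argmax.clear();
  for (int ki = 0; ki < ks.size(); ++ki) {
    int k = ks[ki];
    const arma::mat& W = P.at("conv_W_" + side + "_" + std::to_string(k));
    const arma::mat& bias = P.at("conv_b_" + side + "_" + std::to_string(k));
    arma::mat raw(B, C);
    raw.fill(-arma::datum::inf);
    arma::Mat<int> amax(B, C);
    amax.fill(-1);
    arma::rowvec acc(C);
    for (int b = 0; b < B; ++b) {
      int T = len[b] - k + 1;
      for (int t = 0; t < T; ++t) {
        acc = bias.row(0);
        for (int j = 0; j < k; ++j) {
          int a = X(b, t + j); // 1..20
          acc += W.row(j * ALPHA + a - 1);
        }
        for (int c = 0; c < C; ++c) {
          if (acc[c] > raw(b, c)) { raw(b, c) = acc[c]; amax(b, c) = t; }
        }
      }
    }
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < C; ++c) {
        double v = raw(b, c);
        feat(b, featcol0 + ki * C + c) = (amax(b, c) >= 0 && v > 0) ? v : 0.0;
      }
    cache.rawmax.push_back(raw);
    cache.argmax.push_back(amax);
  }
}

static void conv_side_backward(const MatMap& P, MatMap& G, const std::string& side,
                               const IntegerMatrix& X, const IntegerVector& ks, int C,
                               const arma::mat& dfeat, int featcol0,
                               const ConvCache& cache) {
  int B = X.nrow();
  for (int ki = 0; ki < ks.size(); ++ki) {
    int k = ks[ki];
    arma::mat& gW = G.at("conv_W_" + side + "_" + std::to_string(k));
    arma::mat& gb = G.at("conv_b_" + side + "_" + std::to_string(k));
    const arma::mat& raw = cache.rawmax[ki];
    const arma::Mat<int>& amax = cache.argmax[ki];
    for (int b = 0; b < B; ++b) {
      for (int c = 0; c < C; ++c) {
        int t = amax(b, c);
        if (t < 0 || raw(b, c) <= 0) continue; // ReLU gate / no valid window
        double g = dfeat(b, featcol0 + ki * C + c);
        if (g == 0) continue;
        gb(0, c) += g;
        for (int j = 0; j < k; ++j) {
          int a = X(b, t + j);
          gW(j * ALPHA + a - 1, c) += g;
        }
      }
    }
  }
}

// ---------- recurrent (LSTM) encoder ----------

struct LstmCache {
  arma::cube gates; // B x 4H x L (i | f | g | o, post-activation)
  arma::cube c;     // B x H x L
  arma::cube h;     // B x H x L
};

static void lstm_side_forward(const MatMap& P, const std::string& side,
                              const IntegerMatrix& X, const IntegerVector& len,
                              int E, int H, arma::mat& feat, int featcol0,
                              LstmCache& cache) {
  int B = X.nrow(), L = X.ncol();
  const arma::mat& Emb = P.at("emb_" + side);
  const arma::mat& Wx = P.at("lstm_Wx_" + side);
  const arma::mat& Wh = P.at("lstm_Wh_" + side);
  const arma::mat& bias = P.at("lstm_b_" + side);
  cache.gates.set_size(B, 4 * H, L);
  cache.c.set_size(B, H, L);
  cache.h.set_size(B, H, L);
  arma::mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  arma::mat xemb(B, E);
  for (int t = 0; t < L; ++t) {
    xemb.zeros();
    for (int b = 0; b < B; ++b) {
      int a = X(b, t);
      if (a > 0 && t < len[b]) xemb.row(b) = Emb.row(a - 1);
    }
    arma::mat Z = xemb * Wx + h * Wh;
    Z.each_row() += bias.row(0);
    arma::mat i = 1.0 / (1.0 + arma::exp(-Z.cols(0, H - 1)));
    arma::mat f = 1.0 / (1.0 + arma::exp(-Z.cols(H, 2 * H - 1)));
    arma::mat g = arma::tanh(Z.cols(2 * H, 3 * H - 1));
    arma::mat o = 1.0 / (1.0 + arma::exp(-Z.cols(3 * H, 4 * H - 1)));
    arma::mat c_new = f % c + i % g;
    arma::mat h_new = o % arma::tanh(c_new);
    for (int b = 0; b < B; ++b) {
      if (t >= len[b]) { // inactive: carry state, zero gates in cache
        c_new.row(b) = c.row(b);
        h_new.row(b) = h.row(b);
        i.row(b).zeros(); f.row(b).zeros(); g.row(b).zeros(); o.row(b).zeros();
      }
    }
    cache.gates.slice(t).cols(0, H - 1) = i;
    cache.gates.slice(t).cols(H, 2 * H - 1) = f;
    cache.gates.slice(t).cols(2 * H, 3 * H - 1) = g;
    cache.gates.slice(t).cols(3 * H, 4 * H - 1) = o;
    c = c_new; h = h_new;
    cache.c.slice(t) = c;
    cache.h.slice(t) = h;
  }
  feat.cols(featcol0, featcol0 + H - 1) = h;
}

static void lstm_side_backward(const MatMap& P, MatMap& G, const std::string& side,
                               const IntegerMatrix& X, const IntegerVector& len,
                               int E, int H, const arma::mat& dfeat, int featcol0,
                               const LstmCache& cache) {
  int B = X.nrow(), L = X.ncol();
  const arma::mat& Emb = P.at("emb_" + side);
  const arma::mat& Wx = P.at("lstm_Wx_" + side);
  const arma::mat& Wh = P.at("lstm_Wh_" + side);
  arma::mat& gEmb = G.at("emb_" + side);
  arma::mat& gWx = G.at("lstm_Wx_" + side);
  arma::mat& gWh = G.at("lstm_Wh_" + side);
  arma::mat& gb = G.at("lstm_b_" + side);
  (void)Emb;
  arma::mat dh = dfeat.cols(featcol0, featcol0 + H - 1);
  arma::mat dc(B, H, arma::fill::zeros);
  arma::mat xemb(B, E);
  for (int t = L - 1; t >= 0; --t) {
    const arma::mat i = cache.gates.slice(t).cols(0, H - 1);
    const arma::mat f = cache.gates.slice(t).cols(H, 2 * H - 1);
    const arma::mat g = cache.gates.slice(t).cols(2 * H, 3 * H - 1);
    const arma::mat o = cache.gates.slice(t).cols(3 * H, 4 * H - 1);
    arma::mat c_prev(B, H, arma::fill::zeros), h_prev(B, H, arma::fill::zeros);
    if (t > 0) { c_prev = cache.c.slice(t - 1); h_prev = cache.h.slice(t - 1); }
    arma::mat tc = arma::tanh(cache.c.slice(t));
    arma::mat do_ = dh % tc;
    arma::mat dct = dc + dh % o % (1.0 - tc % tc);
    arma::mat di = dct % g;
    arma::mat dg = dct % i;
    arma::mat df = dct % c_prev;
    arma::mat dc_prev = dct % f;
    arma::mat dz(B, 4 * H);
    dz.cols(0, H - 1) = di % i % (1.0 - i);
    dz.cols(H, 2 * H - 1) = df % f % (1.0 - f);
    dz.cols(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    dz.cols(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    xemb.zeros();
    for (int b = 0; b < B; ++b) {
      if (t >= len[b]) {
        dz.row(b).zeros();            // no computation happened at this step
      } else {
        int a = X(b, t);
        if (a > 0) xemb.row(b) = P.at("emb_" + side).row(a - 1);
      }
    }
    gWx += xemb.t() * dz;
    gWh += h_prev.t() * dz;
    gb.row(0) += arma::sum(dz, 0);
    arma::mat dx = dz * Wx.t();
    arma::mat dh_prev = dz * Wh.t();
    for (int b = 0; b < B; ++b) {
      if (t >= len[b]) {
        // state carried through: gradient passes back unchanged
        dh_prev.row(b) += dh.row(b);
        dc_prev.row(b) = dc.row(b);
      } else {
        int a = X(b, t);
        if (a > 0) gEmb.row(a - 1) += dx.row(b);
      }
    }
    dh = dh_prev;
    dc = dc_prev;
  }
}

// ---------- full model ----------

// [[Rcpp::export]]
List nn_eval(List cfg, NumericVector params,
             IntegerMatrix Xc, IntegerVector lc,
             IntegerMatrix Xp, IntegerVector lp,
             Nullable<NumericVector> y_ = R_NilValue,
             Nullable<NumericMatrix> dropmask_ = R_NilValue,
             bool want_grad = false) {
  std::string family = as<std::string>(cfg["family"]);
  std::vector<PDef> defs = build_layout(cfg);
  size_t nPar = defs.back().offset + (size_t)defs.back().d1 * defs.back().d2;
  if ((size_t)params.size() != nPar)
    stop("parameter vector has length %d, expected %d", (int)params.size(), (int)nPar);
  MatMap P = make_views(defs, params.begin());

  int B = Xc.nrow();
  IntegerVector hl = cfg["head_layers"];

  int F;
  IntegerVector ks;
  int C = 0, E = 0, H = 0;
  if (family == "convolutional") {
    ks = cfg["conv_filter_sizes"];
    C = as<int>(cfg["conv_channels"]);
    F = 2 * ks.size() * C;
  } else {
    E = as<int>(cfg["embed_dim"]);
    H = as<int>(cfg["hidden_dim"]);
    F = 2 * H;
  }

  arma::mat feat(B, F, arma::fill::zeros);
  ConvCache cc_c, cc_p;
  LstmCache lc_c, lc_p;
  if (family == "convolutional") {
    conv_side_forward(P, "cdr3", Xc, lc, ks, C, feat, 0, cc_c);
    conv_side_forward(P, "pep", Xp, lp, ks, C, feat, F / 2, cc_p);
  } else {
    lstm_side_forward(P, "cdr3", Xc, lc, E, H, feat, 0, lc_c);
    lstm_side_forward(P, "pep", Xp, lp, E, H, feat, F / 2, lc_p);
  }

  // dropout (inverted) on the feature vector feeding the head
  arma::mat drop(B, F, arma::fill::ones);
  if (dropmask_.isNotNull()) {
    NumericMatrix dm(dropmask_);
    if (dm.nrow() != B || dm.ncol() != F) stop("dropout mask has wrong shape");
    drop = arma::mat(dm.begin(), B, F, true);
  }

  int nh = hl.size();
  std::vector<arma::mat> acts(nh + 1); // acts[0] = dropped features
  acts[0] = feat % drop;
  std::vector<arma::mat> zs(nh);
  for (int i = 0; i < nh; ++i) {
    arma::mat z = acts[i] * P.at("head_W" + std::to_string(i + 1));
    z.each_row() += P.at("head_b" + std::to_string(i + 1)).row(0);
    zs[i] = z;
    acts[i + 1] = arma::clamp(z, 0.0, arma::datum::inf); // ReLU
  }
  arma::vec logit = acts[nh] * P.at("head_Wout") + P.at("head_bout")(0, 0);
  arma::vec prob = 1.0 / (1.0 + arma::exp(-logit));

  List out;
  out["scores"] = NumericVector(prob.begin(), prob.end());

  if (y_.isNotNull()) {
    NumericVector yv(y_);
    arma::vec y(yv.begin(), B, true);
    arma::vec pc = arma::clamp(prob, 1e-12, 1.0 - 1e-12);
    double loss = arma::mean(-(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc)));
    out["loss"] = loss;

    if (want_grad) {
      NumericVector gflat((R_xlen_t)nPar);
      MatMap G = make_views(defs, gflat.begin());
      arma::vec dlogit = (prob - y) / (double)B;
      G.at("head_Wout") += acts[nh].t() * dlogit;
      G.at("head_bout")(0, 0) += arma::accu(dlogit);
      arma::mat da = dlogit * P.at("head_Wout").t();
      for (int i = nh - 1; i >= 0; --i) {
        arma::mat dz = da % arma::conv_to<arma::mat>::from(zs[i] > 0);
        G.at("head_W" + std::to_string(i + 1)) += acts[i].t() * dz;
        G.at("head_b" + std::to_string(i + 1)).row(0) += arma::sum(dz, 0);
        da = dz * P.at("head_W" + std::to_string(i + 1)).t();
      }
      arma::mat dfeat = da % drop;
      if (family == "convolutional") {
        conv_side_backward(P, G, "cdr3", Xc, ks, C, dfeat, 0, cc_c);
        conv_side_backward(P, G, "pep", Xp, ks, C, dfeat, F / 2, cc_p);
      } else {
        lstm_side_backward(P, G, "cdr3", Xc, lc, E, H, dfeat, 0, lc_c);
        lstm_side_backward(P, G, "pep", Xp, lp, E, H, dfeat, F / 2, lc_p);
      }
      out["grad"] = gflat;
    }
  }
  return out;
}
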