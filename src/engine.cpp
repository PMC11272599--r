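// Training and inference engine for the hybrid 2DCNN-GRU scalogram
// classifier. No deep-learning framework is available in this stack, so the
// forward pass, backpropagation (including BPTT through the GRU) and the
// Adam optimizer with legacy per-update learning-rate decay are implemented
// here directly. Everything is templated on the floating type: float is the
// training default, double backs the finite-difference gradient checks.
//
// Architecture (variant "full"):
//   input (H,H,3)
//   -> 5 x [conv 3x3 same + ReLU -> maxpool 2x2 stride 2], dropout after
//      pools 3, 4, 5
//   -> global average pool -> length-F5 sequence of scalar steps
//   -> GRU (single bias per gate; gate order z, r, candidate)
//   -> dense ReLU -> dense softmax
// "cnn_only" feeds the GAP vector straight into the dense head; "gru_only"
// feeds the image rows (width*3 features per step) into the GRU.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
#include <vector>
#include <string>

using namespace Rcpp;

template <typename T> using TMat = arma::Mat<T>;
template <typename T> using TCol = arma::Col<T>;
template <typename T> using TCube = arma::Cube<T>;

enum Variant { FULL = 0, CNN_ONLY = 1, GRU_ONLY = 2 };

struct NetCfg {
  int variant;
  int H;                     // input height == width
  arma::ivec filters;        // 5 conv filter counts
  int gru_units;
  int dense_units;
  int n_classes;
  arma::vec dropout;         // rates after pools 3, 4, 5
};

static NetCfg parse_cfg(const List& cfg) {
  NetCfg c;
  std::string v = as<std::string>(cfg["variant"]);
  c.variant = v == "full" ? FULL : (v == "cnn_only" ? CNN_ONLY : GRU_ONLY);
  c.H = as<int>(cfg["input_size"]);
  c.filters = as<arma::ivec>(cfg["conv_filters"]);
  c.gru_units = as<int>(cfg["gru_units"]);
  c.dense_units = as<int>(cfg["dense_units"]);
  c.n_classes = as<int>(cfg["n_classes"]);
  c.dropout = as<arma::vec>(cfg["dropout"]);
  return c;
}

// ---- parameters -----------------------------------------------------------

template <typename T>
struct Params {
  std::vector<TMat<T>> conv_w;  // F x 9*Cin
  std::vector<TCol<T>> conv_b;
  TMat<T> Wz, Wr, Wh;           // u x (u + d)
  TCol<T> bz, br, bh;
  TMat<T> Wd1, Wd2;
  TCol<T> bd1, bd2;
  bool has_conv = false, has_gru = false;

  // Pointer lists are built on demand (never cached) so that copying or
  // moving a Params can not leave stale pointers behind.
  std::vector<TMat<T>*> mat_list() {
    std::vector<TMat<T>*> m;
    if (has_conv)
      for (size_t l = 0; l < conv_w.size(); ++l) m.push_back(&conv_w[l]);
    if (has_gru) { m.push_back(&Wz); m.push_back(&Wr); m.push_back(&Wh); }
    m.push_back(&Wd1); m.push_back(&Wd2);
    return m;
  }
  std::vector<TCol<T>*> vec_list() {
    std::vector<TCol<T>*> v;
    if (has_conv)
      for (size_t l = 0; l < conv_b.size(); ++l) v.push_back(&conv_b[l]);
    if (has_gru) { v.push_back(&bz); v.push_back(&br); v.push_back(&bh); }
    v.push_back(&bd1); v.push_back(&bd2);
    return v;
  }
};

template <typename T>
static TMat<T> get_mat(const List& p, const char* nm) {
  return arma::conv_to<TMat<T>>::from(as<arma::mat>(p[nm]));
}
template <typename T>
static TCol<T> get_vec(const List& p, const char* nm) {
  return arma::conv_to<TCol<T>>::from(as<arma::vec>(p[nm]));
}

template <typename T>
static Params<T> params_from_list(const List& p, const NetCfg& cfg) {
  Params<T> pr;
  if (cfg.variant != GRU_ONLY) {
    pr.has_conv = true;
    for (int l = 0; l < 5; ++l) {
      std::string w = "Wc" + std::to_string(l + 1);
      std::string b = "bc" + std::to_string(l + 1);
      pr.conv_w.push_back(get_mat<T>(p, w.c_str()));
      pr.conv_b.push_back(get_vec<T>(p, b.c_str()));
    }
  }
  if (cfg.variant != CNN_ONLY) {
    pr.has_gru = true;
    pr.Wz = get_mat<T>(p, "Wz"); pr.bz = get_vec<T>(p, "bz");
    pr.Wr = get_mat<T>(p, "Wr"); pr.br = get_vec<T>(p, "br");
    pr.Wh = get_mat<T>(p, "Wh"); pr.bh = get_vec<T>(p, "bh");
  }
  pr.Wd1 = get_mat<T>(p, "Wd1"); pr.bd1 = get_vec<T>(p, "bd1");
  pr.Wd2 = get_mat<T>(p, "Wd2"); pr.bd2 = get_vec<T>(p, "bd2");
  return pr;
}

template <typename T>
static List params_to_list(const Params<T>& pr, const NetCfg& cfg) {
  List out;
  if (pr.has_conv)
    for (int l = 0; l < 5; ++l) {
      out["Wc" + std::to_string(l + 1)] =
          wrap(arma::conv_to<arma::mat>::from(pr.conv_w[l]));
      out["bc" + std::to_string(l + 1)] =
          wrap(arma::conv_to<arma::vec>::from(pr.conv_b[l]));
    }
  if (pr.has_gru) {
    out["Wz"] = wrap(arma::conv_to<arma::mat>::from(pr.Wz));
    out["Wr"] = wrap(arma::conv_to<arma::mat>::from(pr.Wr));
    out["Wh"] = wrap(arma::conv_to<arma::mat>::from(pr.Wh));
    out["bz"] = wrap(arma::conv_to<arma::vec>::from(pr.bz));
    out["br"] = wrap(arma::conv_to<arma::vec>::from(pr.br));
    out["bh"] = wrap(arma::conv_to<arma::vec>::from(pr.bh));
  }
  out["Wd1"] = wrap(arma::conv_to<arma::mat>::from(pr.Wd1));
  out["bd1"] = wrap(arma::conv_to<arma::vec>::from(pr.bd1));
  out["Wd2"] = wrap(arma::conv_to<arma::mat>::from(pr.Wd2));
  out["bd2"] = wrap(arma::conv_to<arma::vec>::from(pr.bd2));
  return out;
}

// Zero-initialised gradient holder mirroring a Params.
template <typename T>
static Params<T> zeros_like(const Params<T>& p) {
  Params<T> g;
  g.has_conv = p.has_conv; g.has_gru = p.has_gru;
  if (p.has_conv)
    for (size_t l = 0; l < p.conv_w.size(); ++l) {
      g.conv_w.push_back(TMat<T>(arma::size(p.conv_w[l]), arma::fill::zeros));
      g.conv_b.push_back(TCol<T>(p.conv_b[l].n_elem, arma::fill::zeros));
    }
  if (p.has_gru) {
    g.Wz.zeros(arma::size(p.Wz)); g.bz.zeros(p.bz.n_elem);
    g.Wr.zeros(arma::size(p.Wr)); g.br.zeros(p.br.n_elem);
    g.Wh.zeros(arma::size(p.Wh)); g.bh.zeros(p.bh.n_elem);
  }
  g.Wd1.zeros(arma::size(p.Wd1)); g.bd1.zeros(p.bd1.n_elem);
  g.Wd2.zeros(arma::size(p.Wd2)); g.bd2.zeros(p.bd2.n_elem);
  return g;
}

// ---- im2col / col2im (3x3, same padding) ----------------------------------

// Writes the im2col transpose of `in` into rows [row0, row0 + H*W) of XT.
template <typename T>
static void im2col_into(const TCube<T>& in, TMat<T>& XT, arma::uword row0) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  for (int c = 0; c < C; ++c) {
    const TMat<T>& sl = in.slice(c);
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int r = c * 9 + dj * 3 + di;
        const int i0 = std::max(0, 1 - di), i1 = std::min(H - 1, H - di);
        const int j0 = std::max(0, 1 - dj), j1 = std::min(W - 1, W - dj);
        for (int j = j0; j <= j1; ++j) {
          XT(arma::span(row0 + j * H + i0, row0 + j * H + i1), r) =
              sl(arma::span(i0 + di - 1, i1 + di - 1), j + dj - 1);
        }
      }
    }
  }
}

template <typename T>
static void col2im_add(const TMat<T>& dXT, arma::uword row0, TCube<T>& din) {
  const int H = din.n_rows, W = din.n_cols, C = din.n_slices;
  for (int c = 0; c < C; ++c) {
    TMat<T>& sl = din.slice(c);
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int r = c * 9 + dj * 3 + di;
        const int i0 = std::max(0, 1 - di), i1 = std::min(H - 1, H - di);
        const int j0 = std::max(0, 1 - dj), j1 = std::min(W - 1, W - dj);
        for (int j = j0; j <= j1; ++j) {
          sl(arma::span(i0 + di - 1, i1 + di - 1), j + dj - 1) +=
              dXT(arma::span(row0 + j * H + i0, row0 + j * H + i1), r);
        }
      }
    }
  }
}

// ---- pooling ---------------------------------------------------------------

template <typename T>
static void maxpool(const TCube<T>& in, TCube<T>& out,
                    arma::Cube<arma::uword>& idx) {
  const int H = in.n_rows, W = in.n_cols, F = in.n_slices;
  const int H2 = H / 2, W2 = W / 2;
  out.set_size(H2, W2, F);
  idx.set_size(H2, W2, F);
  for (int f = 0; f < F; ++f) {
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        const int i0 = 2 * i, j0 = 2 * j;
        arma::uword best = i0 + j0 * H;
        T bv = in(i0, j0, f);
        const arma::uword cand[3] = {
          (arma::uword)(i0 + 1 + j0 * H),
          (arma::uword)(i0 + (j0 + 1) * H),
          (arma::uword)(i0 + 1 + (j0 + 1) * H)};
        for (int k = 0; k < 3; ++k) {
          T v = in.slice(f)(cand[k]);
          if (v > bv) { bv = v; best = cand[k]; }
        }
        out(i, j, f) = bv;
        idx(i, j, f) = best;
      }
    }
  }
}

template <typename T>
static void maxpool_back(const TCube<T>& dout,
                         const arma::Cube<arma::uword>& idx, TCube<T>& din) {
  const int H2 = dout.n_rows, W2 = dout.n_cols, F = dout.n_slices;
  for (int f = 0; f < F; ++f)
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i)
        din.slice(f)(idx(i, j, f)) += dout(i, j, f);
}

// ---- activations -----------------------------------------------------------

template <typename T> static TMat<T> sigmoid(const TMat<T>& x) {
  return 1 / (1 + arma::exp(-x));
}

// ---- caches ----------------------------------------------------------------

template <typename T>
struct ConvLayerCache {
  TMat<T> XT;                                   // (B*H*W) x 9Cin
  std::vector<TCube<T>> act;                    // post-ReLU, pre-pool
  std::vector<arma::Cube<arma::uword>> pidx;
  std::vector<TCube<T>> pooled;                 // post-pool (+dropout)
  std::vector<TCube<T>> mask;                   // dropout masks (maybe empty)
  int Hin = 0, Hp = 0, Cin = 0, F = 0;
};

template <typename T>
struct GruCache {
  TCube<T> X;                 // d x B x Tsteps
  TCube<T> Z, R, Ht;          // u x B x Tsteps
  TCube<T> H;                 // u x B x (Tsteps+1), slice 0 = h0 = 0
};

template <typename T>
struct HeadCache {
  TMat<T> in;                 // nin x B
  TMat<T> a1;                 // dense x B (post-ReLU)
  TMat<T> probs;              // ncls x B
};

// ---- forward ---------------------------------------------------------------

template <typename T>
static void conv_stack_forward(const Params<T>& pr, const NetCfg& cfg,
                               const std::vector<TCube<T>>& images,
                               bool training, std::mt19937& rng,
                               std::vector<ConvLayerCache<T>>& caches,
                               TMat<T>& gap) {
  const int B = images.size();
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  caches.assign(5, ConvLayerCache<T>());
  const std::vector<TCube<T>>* cur = &images;
  for (int l = 0; l < 5; ++l) {
    ConvLayerCache<T>& cc = caches[l];
    const int H = (*cur)[0].n_rows, W = (*cur)[0].n_cols,
              C = (*cur)[0].n_slices;
    const int F = pr.conv_w[l].n_rows;
    cc.Hin = H; cc.Cin = C; cc.F = F;
    const arma::uword hw = (arma::uword)H * W;
    cc.XT.zeros(hw * B, 9 * C);
    for (int b = 0; b < B; ++b) im2col_into((*cur)[b], cc.XT, b * hw);
    // Y = W * XT' + b : F x (B*HW)
    TMat<T> Y = pr.conv_w[l] * cc.XT.t();
    Y.each_col() += pr.conv_b[l];
    cc.act.resize(B); cc.pidx.resize(B); cc.pooled.resize(B);
    const bool drop = training && l >= 2 && cfg.dropout(l - 2) > 0;
    if (drop) cc.mask.resize(B);
    for (int b = 0; b < B; ++b) {
      TMat<T> Yb = Y.cols(b * hw, (b + 1) * hw - 1).t(); // HW x F
      cc.act[b] = TCube<T>(Yb.memptr(), H, W, F);
      cc.act[b].transform([](T v) { return v > 0 ? v : (T)0; });
      maxpool(cc.act[b], cc.pooled[b], cc.pidx[b]);
      if (drop) {
        const double p = cfg.dropout(l - 2);
        const T scale = (T)(1.0 / (1.0 - p));
        cc.mask[b].set_size(arma::size(cc.pooled[b]));
        for (arma::uword q = 0; q < cc.mask[b].n_elem; ++q)
          cc.mask[b](q) = unif(rng) < p ? (T)0 : scale;
        cc.pooled[b] %= cc.mask[b];
      }
    }
    cc.Hp = cc.pooled[0].n_rows;
    cur = &cc.pooled;
  }
  // global average pool -> F5 x B
  const int F5 = cfg.filters(4);
  gap.set_size(F5, B);
  const ConvLayerCache<T>& last = caches[4];
  const double denom = (double)last.pooled[0].n_rows * last.pooled[0].n_cols;
  for (int b = 0; b < B; ++b)
    for (int f = 0; f < F5; ++f)
      gap(f, b) = (T)(arma::accu(last.pooled[b].slice(f)) / denom);
}

template <typename T>
static void gru_forward(const Params<T>& pr, const TCube<T>& X,
                        GruCache<T>& gc) {
  const int d = X.n_rows, B = X.n_cols, Tn = X.n_slices;
  const int u = pr.Wz.n_rows;
  gc.X = X;
  gc.Z.set_size(u, B, Tn); gc.R.set_size(u, B, Tn); gc.Ht.set_size(u, B, Tn);
  gc.H.zeros(u, B, Tn + 1);
  TMat<T> M(u + d, B), M2(u + d, B);
  for (int t = 0; t < Tn; ++t) {
    const TMat<T>& hprev = gc.H.slice(t);
    M.rows(0, u - 1) = hprev;
    M.rows(u, u + d - 1) = X.slice(t);
    TMat<T> Z = pr.Wz * M; Z.each_col() += pr.bz; Z = sigmoid(Z);
    TMat<T> R = pr.Wr * M; R.each_col() += pr.br; R = sigmoid(R);
    M2.rows(0, u - 1) = R % hprev;
    M2.rows(u, u + d - 1) = X.slice(t);
    TMat<T> Hc = pr.Wh * M2; Hc.each_col() += pr.bh;
    Hc = arma::tanh(Hc);
    gc.Z.slice(t) = Z; gc.R.slice(t) = R; gc.Ht.slice(t) = Hc;
    gc.H.slice(t + 1) = (1 - Z) % hprev + Z % Hc;
  }
}

template <typename T>
static void head_forward(const Params<T>& pr, const TMat<T>& in,
                         HeadCache<T>& hc) {
  hc.in = in;
  hc.a1 = pr.Wd1 * in;
  hc.a1.each_col() += pr.bd1;
  hc.a1.transform([](T v) { return v > 0 ? v : (T)0; });
  TMat<T> logits = pr.Wd2 * hc.a1;
  logits.each_col() += pr.bd2;
  logits.each_row() -= arma::max(logits, 0);
  hc.probs = arma::exp(logits);
  hc.probs.each_row() /= arma::sum(hc.probs, 0);
}

// Full forward pass over one batch. Returns class probabilities ncls x B.
template <typename T>
static TMat<T> net_forward(const Params<T>& pr, const NetCfg& cfg,
                           const std::vector<TCube<T>>& images, bool training,
                           std::mt19937& rng,
                           std::vector<ConvLayerCache<T>>& conv_caches,
                           GruCache<T>& gc, HeadCache<T>& hc) {
  const int B = images.size();
  TMat<T> head_in;
  if (cfg.variant != GRU_ONLY) {
    TMat<T> gap;
    conv_stack_forward(pr, cfg, images, training, rng, conv_caches, gap);
    if (cfg.variant == FULL) {
      // reshape the GAP vector into a length-F5 sequence of scalar steps
      const int F5 = gap.n_rows;
      TCube<T> X(1, B, F5);
      for (int t = 0; t < F5; ++t) X.slice(t) = gap.row(t);
      gru_forward(pr, X, gc);
      head_in = gc.H.slice(F5);
    } else {
      head_in = gap;
    }
  } else {
    // rows of the image as a sequence: H steps of width*3 features
    const int H = images[0].n_rows, W = images[0].n_cols,
              C = images[0].n_slices;
    TCube<T> X(W * C, B, H);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < H; ++t)
        for (int c = 0; c < C; ++c)
          for (int j = 0; j < W; ++j)
            X(c * W + j, b, t) = images[b](t, j, c);
    gru_forward(pr, X, gc);
    head_in = gc.H.slice(H);
  }
  head_forward(pr, head_in, hc);
  return hc.probs;
}

// ---- backward --------------------------------------------------------------

template <typename T>
static TMat<T> head_backward(const Params<T>& pr, const HeadCache<T>& hc,
                             const arma::ivec& y, Params<T>& g) {
  const int B = hc.probs.n_cols;
  TMat<T> dlog = hc.probs;
  for (int b = 0; b < B; ++b) dlog(y(b), b) -= (T)1;
  dlog /= (T)B;
  g.Wd2 += dlog * hc.a1.t();
  g.bd2 += arma::sum(dlog, 1);
  TMat<T> da1 = pr.Wd2.t() * dlog;
  da1 %= arma::conv_to<TMat<T>>::from(hc.a1 > 0);
  g.Wd1 += da1 * hc.in.t();
  g.bd1 += arma::sum(da1, 1);
  return pr.Wd1.t() * da1;
}

// BPTT; returns gradient w.r.t. the input sequence (d x B x Tsteps).
template <typename T>
static TCube<T> gru_backward(const Params<T>& pr, const GruCache<T>& gc,
                             const TMat<T>& dh_final, Params<T>& g) {
  const int d = gc.X.n_rows, B = gc.X.n_cols, Tn = gc.X.n_slices;
  const int u = pr.Wz.n_rows;
  TCube<T> dX(d, B, Tn, arma::fill::zeros);
  TMat<T> dh = dh_final;
  TMat<T> M(u + d, B), M2(u + d, B);
  for (int t = Tn - 1; t >= 0; --t) {
    const TMat<T>& hprev = gc.H.slice(t);
    const TMat<T>& Z = gc.Z.slice(t);
    const TMat<T>& R = gc.R.slice(t);
    const TMat<T>& Hc = gc.Ht.slice(t);
    M.rows(0, u - 1) = hprev;
    M.rows(u, u + d - 1) = gc.X.slice(t);
    M2.rows(0, u - 1) = R % hprev;
    M2.rows(u, u + d - 1) = gc.X.slice(t);

    TMat<T> dhc = dh % Z;
    TMat<T> dz = dh % (Hc - hprev);
    TMat<T> dhprev = dh % (1 - Z);

    TMat<T> dah = dhc % (1 - Hc % Hc);
    g.Wh += dah * M2.t();
    g.bh += arma::sum(dah, 1);
    TMat<T> dM2 = pr.Wh.t() * dah;
    TMat<T> drh = dM2.rows(0, u - 1);
    TMat<T> dr = drh % hprev;
    dhprev += drh % R;
    dX.slice(t) += dM2.rows(u, u + d - 1);

    TMat<T> daz = dz % Z % (1 - Z);
    TMat<T> dar = dr % R % (1 - R);
    g.Wz += daz * M.t();
    g.bz += arma::sum(daz, 1);
    g.Wr += dar * M.t();
    g.br += arma::sum(dar, 1);
    TMat<T> dM = pr.Wz.t() * daz + pr.Wr.t() * dar;
    dhprev += dM.rows(0, u - 1);
    dX.slice(t) += dM.rows(u, u + d - 1);

    dh = dhprev;
  }
  return dX;
}

template <typename T>
static void conv_stack_backward(const Params<T>& pr, const NetCfg& cfg,
                                const std::vector<TCube<T>>& images,
                                std::vector<ConvLayerCache<T>>& caches,
                                const TMat<T>& dgap, Params<T>& g) {
  const int B = images.size();
  // GAP backward
  const ConvLayerCache<T>& last = caches[4];
  const int Hp = last.pooled[0].n_rows, Wp = last.pooled[0].n_cols;
  const T denom = (T)1 / (T)(Hp * Wp);
  std::vector<TCube<T>> dpooled(B);
  for (int b = 0; b < B; ++b) {
    dpooled[b].set_size(Hp, Wp, last.F);
    for (int f = 0; f < last.F; ++f)
      dpooled[b].slice(f).fill(dgap(f, b) * denom);
  }
  for (int l = 4; l >= 0; --l) {
    ConvLayerCache<T>& cc = caches[l];
    const int H = cc.Hin, F = cc.F;
    const arma::uword hw = (arma::uword)H * H; // square maps throughout
    TMat<T> dYt(hw * B, F);
    for (int b = 0; b < B; ++b) {
      if (!cc.mask.empty()) dpooled[b] %= cc.mask[b];
      TCube<T> dact(H, H, F, arma::fill::zeros);
      maxpool_back(dpooled[b], cc.pidx[b], dact);
      dact %= arma::conv_to<TCube<T>>::from(cc.act[b] > 0);
      for (int f = 0; f < F; ++f)
        dYt(arma::span(b * hw, (b + 1) * hw - 1), (arma::uword)f) =
            arma::vectorise(dact.slice(f));
    }
    g.conv_w[l] += dYt.t() * cc.XT;
    g.conv_b[l] += arma::sum(dYt, 0).t();
    if (l > 0) { // input gradient not needed for the image itself
      TMat<T> dXT = dYt * pr.conv_w[l];
      std::vector<TCube<T>>& prev = caches[l - 1].pooled;
      dpooled.assign(B, TCube<T>());
      for (int b = 0; b < B; ++b) {
        dpooled[b].zeros(arma::size(prev[b]));
        col2im_add(dXT, b * hw, dpooled[b]);
      }
    }
  }
}

// loss + gradient on one batch; probs returned for metrics
template <typename T>
static double net_loss_grad(const Params<T>& pr, const NetCfg& cfg,
                            const std::vector<TCube<T>>& images,
                            const arma::ivec& y, bool training,
                            std::mt19937& rng, Params<T>* grad,
                            TMat<T>* probs_out) {
  std::vector<ConvLayerCache<T>> conv_caches;
  GruCache<T> gc;
  HeadCache<T> hc;
  TMat<T> probs =
      net_forward(pr, cfg, images, training, rng, conv_caches, gc, hc);
  const int B = images.size();
  double loss = 0;
  for (int b = 0; b < B; ++b) {
    double p = std::max((double)probs(y(b), b), 1e-12);
    loss -= std::log(p);
  }
  loss /= B;
  if (probs_out) *probs_out = probs;
  if (grad) {
    TMat<T> dhead = head_backward(pr, hc, y, *grad);
    if (cfg.variant == FULL) {
      TCube<T> dX = gru_backward(pr, gc, dhead, *grad);
      const int F5 = cfg.filters(4);
      TMat<T> dgap(F5, B);
      for (int t = 0; t < F5; ++t) dgap.row(t) = dX.slice(t).row(0);
      conv_stack_backward(pr, cfg, images, conv_caches, dgap, *grad);
    } else if (cfg.variant == CNN_ONLY) {
      conv_stack_backward(pr, cfg, images, conv_caches, dhead, *grad);
    } else {
      gru_backward(pr, gc, dhead, *grad); // dX w.r.t. raw pixels discarded
    }
  }
  return loss;
}

// ---- data conversion -------------------------------------------------------

template <typename T>
static std::vector<TCube<T>> images_from_r(const NumericVector& X) {
  IntegerVector dim = X.attr("dim");
  if (dim.size() != 4) stop("image array must have dim (H, W, C, N)");
  const int H = dim[0], W = dim[1], C = dim[2], N = dim[3];
  const double* ptr = X.begin();
  std::vector<TCube<T>> out(N);
  const arma::uword per = (arma::uword)H * W * C;
  for (int n = 0; n < N; ++n) {
    out[n].set_size(H, W, C);
    const double* src = ptr + (arma::uword)n * per;
    for (arma::uword q = 0; q < per; ++q) out[n](q) = (T)src[q];
  }
  return out;
}

// ---- Adam ------------------------------------------------------------------

template <typename T>
struct Adam {
  std::vector<TMat<T>> m_m, v_m;
  std::vector<TCol<T>> m_v, v_v;
  double beta1 = 0.9, beta2 = 0.999, eps = 1e-7;
  long iter = 0;

  void init(Params<T>& p) {
    for (auto* w : p.mat_list()) {
      m_m.push_back(TMat<T>(arma::size(*w), arma::fill::zeros));
      v_m.push_back(TMat<T>(arma::size(*w), arma::fill::zeros));
    }
    for (auto* b : p.vec_list()) {
      m_v.push_back(TCol<T>(b->n_elem, arma::fill::zeros));
      v_v.push_back(TCol<T>(b->n_elem, arma::fill::zeros));
    }
  }

  void step(Params<T>& p, Params<T>& g, double lr, double decay) {
    const double lr_t = lr / (1.0 + decay * iter); // legacy per-update decay
    const double t = iter + 1.0;
    const double corr =
        std::sqrt(1.0 - std::pow(beta2, t)) / (1.0 - std::pow(beta1, t));
    const T a = (T)(lr_t * corr);
    auto pm = p.mat_list(); auto gm = g.mat_list();
    auto pv = p.vec_list(); auto gv = g.vec_list();
    for (size_t k = 0; k < pm.size(); ++k) {
      m_m[k] = (T)beta1 * m_m[k] + (T)(1 - beta1) * (*gm[k]);
      v_m[k] = (T)beta2 * v_m[k] + (T)(1 - beta2) * arma::square(*gm[k]);
      *pm[k] -= a * m_m[k] / (arma::sqrt(v_m[k]) + (T)eps);
      m_v[k] = (T)beta1 * m_v[k] + (T)(1 - beta1) * (*gv[k]);
      v_v[k] = (T)beta2 * v_v[k] + (T)(1 - beta2) * arma::square(*gv[k]);
      *pv[k] -= a * m_v[k] / (arma::sqrt(v_v[k]) + (T)eps);
    }
    ++iter;
  }
};

// ---- evaluation helper -----------------------------------------------------

template <typename T>
static void eval_set(const Params<T>& pr, const NetCfg& cfg,
                     const std::vector<TCube<T>>& images, const arma::ivec& y,
                     std::mt19937& rng, double& loss, double& acc) {
  const int N = images.size();
  const int chunk = 32;
  double lsum = 0; int ncorrect = 0;
  for (int s = 0; s < N; s += chunk) {
    const int e = std::min(N, s + chunk);
    std::vector<TCube<T>> batch(images.begin() + s, images.begin() + e);
    std::vector<ConvLayerCache<T>> cc;
    GruCache<T> gc; HeadCache<T> hc;
    TMat<T> probs = net_forward(pr, cfg, batch, false, rng, cc, gc, hc);
    for (int b = 0; b < e - s; ++b) {
      lsum -= std::log(std::max((double)probs(y(s + b), b), 1e-12));
      if ((int)arma::index_max(probs.col(b)) == y(s + b)) ++ncorrect;
    }
  }
  loss = lsum / N;
  acc = (double)ncorrect / N;
}

// ---- exported entry points -------------------------------------------------

template <typename T>
static List train_impl(List params, List cfg_list, NumericVector Xtr,
                       IntegerVector ytr, NumericVector Xval,
                       IntegerVector yval, List train_cfg) {
  NetCfg cfg = parse_cfg(cfg_list);
  Params<T> pr = params_from_list<T>(params, cfg);
  const double lr = as<double>(train_cfg["learning_rate"]);
  const double decay = as<double>(train_cfg["decay"]);
  const int batch = as<int>(train_cfg["batch_size"]);
  const int epochs = as<int>(train_cfg["epochs"]);
  const unsigned seed = (unsigned)as<int>(train_cfg["seed"]);

  std::vector<TCube<T>> imtr = images_from_r<T>(Xtr);
  std::vector<TCube<T>> imval = images_from_r<T>(Xval);
  arma::ivec ytrv = as<arma::ivec>(ytr);
  arma::ivec yvalv = as<arma::ivec>(yval);
  const int N = imtr.size();

  std::mt19937 rng(seed);
  Adam<T> opt;
  opt.init(pr);
  arma::mat history(epochs, 4);
  Params<T> best = pr;
  double best_acc = -1;
  int best_epoch = 0;
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double lsum = 0; int ncorrect = 0, nseen = 0;
    for (int s = 0; s < N; s += batch) {
      const int e = std::min(N, s + batch);
      std::vector<TCube<T>> bim;
      arma::ivec by(e - s);
      for (int b = s; b < e; ++b) {
        bim.push_back(imtr[order[b]]);
        by(b - s) = ytrv(order[b]);
      }
      Params<T> g = zeros_like(pr);
      TMat<T> probs;
      double l = net_loss_grad(pr, cfg, bim, by, true, rng, &g, &probs);
      lsum += l * (e - s);
      for (int b = 0; b < e - s; ++b)
        if ((int)arma::index_max(probs.col(b)) == by(b)) ++ncorrect;
      nseen += e - s;
      opt.step(pr, g, lr, decay);
    }
    double vloss = 0, vacc = 0;
    if (!imval.empty()) eval_set(pr, cfg, imval, yvalv, rng, vloss, vacc);
    history(ep, 0) = lsum / nseen;
    history(ep, 1) = (double)ncorrect / nseen;
    history(ep, 2) = vloss;
    history(ep, 3) = vacc;
    if (vacc > best_acc) { best_acc = vacc; best = pr; best_epoch = ep + 1; }
    Rcpp::checkUserInterrupt();
  }
  if (imval.empty()) { best = pr; best_epoch = epochs; }
  return List::create(
      _["params"] = params_to_list(pr, cfg),
      _["best_params"] = params_to_list(best, cfg),
      _["history"] = wrap(history), _["best_epoch"] = best_epoch);
}

// [[Rcpp::export]]
List cpp_train(List params, List cfg, NumericVector Xtr, IntegerVector ytr,
               NumericVector Xval, IntegerVector yval, List train_cfg,
               std::string precision) {
  if (precision == "double")
    return train_impl<double>(params, cfg, Xtr, ytr, Xval, yval, train_cfg);
  return train_impl<float>(params, cfg, Xtr, ytr, Xval, yval, train_cfg);
}

template <typename T>
static NumericMatrix predict_impl(List params, List cfg_list, NumericVector X) {
  NetCfg cfg = parse_cfg(cfg_list);
  Params<T> pr = params_from_list<T>(params, cfg);
  std::vector<TCube<T>> im = images_from_r<T>(X);
  const int N = im.size();
  NumericMatrix out(N, cfg.n_classes);
  std::mt19937 rng(0);
  const int chunk = 32;
  for (int s = 0; s < N; s += chunk) {
    const int e = std::min(N, s + chunk);
    std::vector<TCube<T>> batch(im.begin() + s, im.begin() + e);
    std::vector<ConvLayerCache<T>> cc;
    GruCache<T> gc; HeadCache<T> hc;
    TMat<T> probs = net_forward(pr, cfg, batch, false, rng, cc, gc, hc);
    for (int b = 0; b < e - s; ++b)
      for (int k = 0; k < cfg.n_classes; ++k) out(s + b, k) = probs(k, b);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_predict(List params, List cfg, NumericVector X,
                          std::string precision) {
  if (precision == "double") return predict_impl<double>(params, cfg, X);
  return predict_impl<float>(params, cfg, X);
}

template <typename T>
static List loss_grad_impl(List params, List cfg_list, NumericVector X,
                           IntegerVector y) {
  NetCfg cfg = parse_cfg(cfg_list);
  Params<T> pr = params_from_list<T>(params, cfg);
  std::vector<TCube<T>> im = images_from_r<T>(X);
  arma::ivec yv = as<arma::ivec>(y);
  std::mt19937 rng(0);
  Params<T> g = zeros_like(pr);
  double loss =
      net_loss_grad<T>(pr, cfg, im, yv, false, rng, &g, (TMat<T>*)nullptr);
  return List::create(_["loss"] = loss, _["grads"] = params_to_list(g, cfg));
}

// [[Rcpp::export]]
List cpp_loss_grad(List params, List cfg, NumericVector X, IntegerVector y,
                   std::string precision) {
  if (precision == "double") return loss_grad_impl<double>(params, cfg, X, y);
  return loss_grad_impl<float>(params, cfg, X, y);
}

// One GRU step with the engine's own cell (single bias per gate), exposed so
// the reference implementation can be checked against the trained network's
// cell.
template <typename T>
static List gru_cell_impl(const arma::mat& Wz, const arma::mat& Wr,
                          const arma::mat& Wh, const arma::vec& bz,
                          const arma::vec& br, const arma::vec& bh,
                          const arma::vec& h_prev, const arma::vec& x) {
  Params<T> pr;
  pr.has_gru = true;
  pr.Wz = arma::conv_to<TMat<T>>::from(Wz);
  pr.Wr = arma::conv_to<TMat<T>>::from(Wr);
  pr.Wh = arma::conv_to<TMat<T>>::from(Wh);
  pr.bz = arma::conv_to<TCol<T>>::from(bz);
  pr.br = arma::conv_to<TCol<T>>::from(br);
  pr.bh = arma::conv_to<TCol<T>>::from(bh);
  const int d = x.n_elem, u = h_prev.n_elem;
  TMat<T> M(u + d, 1), M2(u + d, 1);
  TMat<T> hprev(arma::conv_to<TCol<T>>::from(h_prev));
  TMat<T> xv(arma::conv_to<TCol<T>>::from(x));
  M.rows(0, u - 1) = hprev;
  M.rows(u, u + d - 1) = xv;
  TMat<T> Z = pr.Wz * M; Z.each_col() += pr.bz; Z = sigmoid(Z);
  TMat<T> R = pr.Wr * M; R.each_col() += pr.br; R = sigmoid(R);
  M2.rows(0, u - 1) = R % hprev;
  M2.rows(u, u + d - 1) = xv;
  TMat<T> Hc = pr.Wh * M2; Hc.each_col() += pr.bh;
  Hc = arma::tanh(Hc);
  TMat<T> Hn = (1 - Z) % hprev + Z % Hc;
  return List::create(
      _["z"] = wrap(arma::conv_to<arma::vec>::from(Z.col(0))),
      _["r"] = wrap(arma::conv_to<arma::vec>::from(R.col(0))),
      _["h_tilde"] = wrap(arma::conv_to<arma::vec>::from(Hc.col(0))),
      _["h"] = wrap(arma::conv_to<arma::vec>::from(Hn.col(0))));
}

// [[Rcpp::export]]
List cpp_gru_cell(arma::mat Wz, arma::mat Wr, arma::mat Wh, arma::vec bz,
                  arma::vec br, arma::vec bh, arma::vec h_prev, arma::vec x,
                  std::string precision) {
  if (precision == "double")
    return gru_cell_impl<double>(Wz, Wr, Wh, bz, br, bh, h_prev, x);
  return gru_cell_impl<float>(Wz, Wr, Wh, bz, br, bh, h_prev, x);
}
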