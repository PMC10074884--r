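// Bidirectional LSTM per-position codon classifier: forward pass,
// backpropagation through time, and Adam training. Parameters live in a
// flat list of matrices; layout per layer l (0-based):
//   M[6l+0] Wx_f (4H x Fin)   M[6l+1] Wh_f (4H x H)   M[6l+2] b_f (4H x 1)
//   M[6l+3] Wx_b              M[6l+4] Wh_b            M[6l+5] b_b
// then M[6L] = V (C x 2H), M[6L+1] = c (C x 1).
// All randomness (shuffling, dropout) is drawn from R's RNG so that a
// set.seed() on the R side makes training fully reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef std::vector<arma::mat> Params;

static Params unpack(const List& w) {
  Params M;
  List layers = w["layers"];
  for (R_xlen_t l = 0; l < layers.size(); ++l) {
    List ly = layers[l];
    M.push_back(as<arma::mat>(ly["Wx_f"]));
    M.push_back(as<arma::mat>(ly["Wh_f"]));
    M.push_back(as<arma::mat>(ly["b_f"]));
    M.push_back(as<arma::mat>(ly["Wx_b"]));
    M.push_back(as<arma::mat>(ly["Wh_b"]));
    M.push_back(as<arma::mat>(ly["b_b"]));
  }
  M.push_back(as<arma::mat>(w["V"]));
  M.push_back(as<arma::mat>(w["c"]));
  return M;
}

static List pack(const Params& M) {
  int L = ((int)M.size() - 2) / 6;
  List layers(L);
  for (int l = 0; l < L; ++l) {
    layers[l] = List::create(
      Named("Wx_f") = M[6 * l + 0], Named("Wh_f") = M[6 * l + 1],
      Named("b_f") = M[6 * l + 2], Named("Wx_b") = M[6 * l + 3],
      Named("Wh_b") = M[6 * l + 4], Named("b_b") = M[6 * l + 5]);
  }
  return List::create(Named("layers") = layers,
                      Named("V") = M[6 * L], Named("c") = M[6 * L + 1]);
}

static Params zeros_like(const Params& M) {
  Params Z;
  for (size_t i = 0; i < M.size(); ++i) {
    Z.push_back(arma::zeros<arma::mat>(M[i].n_rows, M[i].n_cols));
  }
  return Z;
}

struct DirCache { arma::mat i, f, g, o, c, tc, h; };

// One LSTM direction over the full sequence. X is Fin x T; column t of the
// caches corresponds to absolute position t regardless of direction.
static void forward_dir(const arma::mat& Wx, const arma::mat& Wh,
                        const arma::mat& b, const arma::mat& X, bool rev,
                        DirCache& K) {
  int T = X.n_cols, H = Wh.n_cols;
  K.i.set_size(H, T); K.f.set_size(H, T); K.g.set_size(H, T);
  K.o.set_size(H, T); K.c.set_size(H, T); K.tc.set_size(H, T);
  K.h.set_size(H, T);
  arma::vec hprev(H, arma::fill::zeros), cprev(H, arma::fill::zeros);
  for (int s = 0; s < T; ++s) {
    int t = rev ? T - 1 - s : s;
    arma::vec z = Wx * X.col(t) + Wh * hprev + b.col(0);
    arma::vec ii = 1.0 / (1.0 + arma::exp(-z.subvec(0, H - 1)));
    arma::vec ff = 1.0 / (1.0 + arma::exp(-z.subvec(H, 2 * H - 1)));
    arma::vec gg = arma::tanh(z.subvec(2 * H, 3 * H - 1));
    arma::vec oo = 1.0 / (1.0 + arma::exp(-z.subvec(3 * H, 4 * H - 1)));
    arma::vec cc = ff % cprev + ii % gg;
    arma::vec tc = arma::tanh(cc);
    K.i.col(t) = ii; K.f.col(t) = ff; K.g.col(t) = gg; K.o.col(t) = oo;
    K.c.col(t) = cc; K.tc.col(t) = tc;
    K.h.col(t) = oo % tc;
    hprev = K.h.col(t); cprev = cc;
  }
}

// BPTT for one direction. dH is dLoss/dh at every position; accumulates
// parameter gradients into gWx/gWh/gb and input gradients into dX.
static void backward_dir(const arma::mat& Wx, const arma::mat& Wh,
                         const arma::mat& X, bool rev, const DirCache& K,
                         const arma::mat& dH, arma::mat& gWx, arma::mat& gWh,
                         arma::mat& gb, arma::mat& dX) {
  int T = X.n_cols, H = Wh.n_cols;
  arma::vec dh_next(H, arma::fill::zeros), dc_next(H, arma::fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    int t = rev ? T - 1 - s : s;
    arma::vec hprev(H, arma::fill::zeros), cprev(H, arma::fill::zeros);
    if (s > 0) {
      int tp = rev ? T - s : s - 1;
      hprev = K.h.col(tp);
      cprev = K.c.col(tp);
    }
    arma::vec dh = dH.col(t) + dh_next;
    arma::vec tc = K.tc.col(t);
    arma::vec doo = dh % tc;
    arma::vec dc = dc_next + dh % K.o.col(t) % (1.0 - tc % tc);
    arma::vec dzi = (dc % K.g.col(t)) % K.i.col(t) % (1.0 - K.i.col(t));
    arma::vec dzf = (dc % cprev) % K.f.col(t) % (1.0 - K.f.col(t));
    arma::vec dzg = (dc % K.i.col(t)) % (1.0 - K.g.col(t) % K.g.col(t));
    arma::vec dzo = doo % K.o.col(t) % (1.0 - K.o.col(t));
    arma::vec dz = arma::join_cols(arma::join_cols(dzi, dzf),
                                   arma::join_cols(dzg, dzo));
    gWx += dz * X.col(t).t();
    gWh += dz * hprev.t();
    gb += dz;
    dX.col(t) += Wx.t() * dz;
    dh_next = Wh.t() * dz;
    dc_next = dc % K.f.col(t);
  }
}

struct SeqCache {
  std::vector<arma::mat> inputs;   // input to each layer, Fin x T
  std::vector<DirCache> fw, bw;
  std::vector<arma::mat> masks;    // dropout masks on layer outputs
  arma::mat D;                     // representation fed to the dense head
  arma::mat logp;                  // log-softmax scores, C x T
};

// Full network forward; fills the cache. Dropout masks are drawn from R's
// RNG when training && dropout > 0 (inverted dropout).
static void forward_net(const Params& M, int L, const arma::mat& X0,
                        double dropout, bool training, SeqCache& S) {
  arma::mat cur = X0;
  S.inputs.clear(); S.fw.assign(L, DirCache()); S.bw.assign(L, DirCache());
  S.masks.clear();
  for (int l = 0; l < L; ++l) {
    S.inputs.push_back(cur);
    forward_dir(M[6 * l + 0], M[6 * l + 1], M[6 * l + 2], cur, false, S.fw[l]);
    forward_dir(M[6 * l + 3], M[6 * l + 4], M[6 * l + 5], cur, true, S.bw[l]);
    arma::mat out = arma::join_cols(S.fw[l].h, S.bw[l].h);
    if (training && dropout > 0.0) {
      arma::mat mask(out.n_rows, out.n_cols);
      double keep = 1.0 - dropout;
      for (arma::uword j = 0; j < mask.n_elem; ++j) {
        mask(j) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
      }
      out %= mask;
      S.masks.push_back(mask);
    } else {
      S.masks.push_back(arma::mat());
    }
    cur = out;
  }
  S.D = cur;
  const arma::mat& V = M[6 * L];
  const arma::mat& c = M[6 * L + 1];
  arma::mat Z = V * cur;
  Z.each_col() += c.col(0);
  // column-wise log-softmax
  arma::rowvec mx = arma::max(Z, 0);
  Z.each_row() -= mx;
  arma::rowvec lse = arma::log(arma::sum(arma::exp(Z), 0));
  Z.each_row() -= lse;
  S.logp = Z;
}

// Cross-entropy of cached log-probs against labels; also argmax hits.
static void score_cache(const SeqCache& S, const arma::ivec& y,
                        double& nll, int& hits) {
  for (arma::uword t = 0; t < y.n_elem; ++t) {
    nll -= S.logp(y(t), t);
    arma::uword am = arma::index_max(S.logp.col(t));
    if ((int)am == y(t)) ++hits;
  }
}

// Backprop one sequence; gradients scaled by `scale` are accumulated in G.
static void backward_net(const Params& M, int L, const SeqCache& S,
                         const arma::ivec& y, double scale, Params& G) {
  arma::mat dZ = arma::exp(S.logp);          // softmax probs
  for (arma::uword t = 0; t < y.n_elem; ++t) dZ(y(t), t) -= 1.0;
  dZ *= scale;
  G[6 * L] += dZ * S.D.t();
  G[6 * L + 1] += arma::sum(dZ, 1);
  arma::mat dCur = M[6 * L].t() * dZ;
  for (int l = L - 1; l >= 0; --l) {
    if (S.masks[l].n_elem > 0) dCur %= S.masks[l];
    int H = M[6 * l + 1].n_cols;
    arma::mat dHf = dCur.rows(0, H - 1);
    arma::mat dHb = dCur.rows(H, 2 * H - 1);
    arma::mat dX(S.inputs[l].n_rows, S.inputs[l].n_cols, arma::fill::zeros);
    backward_dir(M[6 * l + 0], M[6 * l + 1], S.inputs[l], false, S.fw[l],
                 dHf, G[6 * l + 0], G[6 * l + 1], G[6 * l + 2], dX);
    backward_dir(M[6 * l + 3], M[6 * l + 4], S.inputs[l], true, S.bw[l],
                 dHb, G[6 * l + 3], G[6 * l + 4], G[6 * l + 5], dX);
    dCur = dX;
  }
}

static bool is_bias(size_t idx, size_t n_params) {
  if (idx == n_params - 1) return true;          // dense bias c
  if (idx == n_params - 2) return false;         // V
  return idx % 6 == 2 || idx % 6 == 5;           // b_f, b_b
}

static std::vector<arma::mat> to_arma_X(const List& X_list) {
  std::vector<arma::mat> X;
  for (R_xlen_t i = 0; i < X_list.size(); ++i) {
    X.push_back(as<arma::mat>(X_list[i]).t());   // R gives T x F
  }
  return X;
}

static std::vector<arma::ivec> to_arma_y(const List& y_list) {
  std::vector<arma::ivec> y;
  for (R_xlen_t i = 0; i < y_list.size(); ++i) {
    arma::ivec v = as<arma::ivec>(y_list[i]);
    y.push_back(v - 1);                          // R labels are 1-based
  }
  return y;
}

// [[Rcpp::export]]
List cpp_bilstm_train(List weights, List X_list, List y_list,
                      List Xval_list, List yval_list, int epochs, double lr,
                      double l2, double dropout, int batch_size) {
  Params M = unpack(weights);
  int L = ((int)M.size() - 2) / 6;
  std::vector<arma::mat> X = to_arma_X(X_list);
  std::vector<arma::ivec> y = to_arma_y(y_list);
  std::vector<arma::mat> Xv = to_arma_X(Xval_list);
  std::vector<arma::ivec> yv = to_arma_y(yval_list);
  int n = (int)X.size();
  if (n == 0) stop("empty training set");

  Params mAdam = zeros_like(M), vAdam = zeros_like(M);
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  std::vector<double> tr_loss, tr_acc, va_loss, va_acc;
  Params best = M;
  double best_val = R_PosInf;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle from R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double ep_nll = 0.0; long ep_pos = 0; int ep_hits = 0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(n, start + batch_size);
      long batch_pos = 0;
      for (int k = start; k < end; ++k) batch_pos += X[order[k]].n_cols;
      if (batch_pos == 0) continue;
      Params G = zeros_like(M);
      for (int k = start; k < end; ++k) {
        const arma::mat& Xi = X[order[k]];
        const arma::ivec& yi = y[order[k]];
        if (Xi.n_cols == 0) continue;
        SeqCache S;
        forward_net(M, L, Xi, dropout, true, S);
        score_cache(S, yi, ep_nll, ep_hits);
        backward_net(M, L, S, yi, 1.0 / (double)batch_pos, G);
      }
      ep_pos += batch_pos;
      ++step;
      double c1 = 1.0 - std::pow(b1, (double)step);
      double c2 = 1.0 - std::pow(b2, (double)step);
      for (size_t p = 0; p < M.size(); ++p) {
        arma::mat g = G[p];
        if (l2 > 0 && !is_bias(p, M.size())) g += l2 * M[p];
        mAdam[p] = b1 * mAdam[p] + (1.0 - b1) * g;
        vAdam[p] = b2 * vAdam[p] + (1.0 - b2) * (g % g);
        M[p] -= lr * (mAdam[p] / c1) / (arma::sqrt(vAdam[p] / c2) + eps);
      }
    }
    tr_loss.push_back(ep_pos ? ep_nll / ep_pos : NA_REAL);
    tr_acc.push_back(ep_pos ? (double)ep_hits / ep_pos : NA_REAL);

    if (!Xv.empty()) {
      double v_nll = 0.0; long v_pos = 0; int v_hits = 0;
      for (size_t k = 0; k < Xv.size(); ++k) {
        if (Xv[k].n_cols == 0) continue;
        SeqCache S;
        forward_net(M, L, Xv[k], 0.0, false, S);
        score_cache(S, yv[k], v_nll, v_hits);
        v_pos += Xv[k].n_cols;
      }
      double vl = v_pos ? v_nll / v_pos : NA_REAL;
      va_loss.push_back(vl);
      va_acc.push_back(v_pos ? (double)v_hits / v_pos : NA_REAL);
      if (vl < best_val) { best_val = vl; best = M; }
    } else {
      va_loss.push_back(NA_REAL);
      va_acc.push_back(NA_REAL);
      best = M;   // no validation set: keep the final parameters
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
    Named("weights") = pack(best),
    Named("final_weights") = pack(M),
    Named("history") = DataFrame::create(
      Named("epoch") = seq(1, epochs),
      Named("train_loss") = tr_loss, Named("train_accuracy") = tr_acc,
      Named("val_loss") = va_loss, Named("val_accuracy") = va_acc));
}

// [[Rcpp::export]]
arma::mat cpp_bilstm_predict(List weights, arma::mat X) {
  Params M = unpack(weights);
  int L = ((int)M.size() - 2) / 6;
  SeqCache S;
  forward_net(M, L, X.t(), 0.0, false, S);
  return arma::exp(S.logp).t();   // T x C probabilities
}

// Mean per-position loss and full gradients on a batch, without dropout or
// any update. Used by the finite-difference gradient check.
// [[Rcpp::export]]
List cpp_bilstm_loss_grad(List weights, List X_list, List y_list, double l2) {
  Params M = unpack(weights);
  int L = ((int)M.size() - 2) / 6;
  std::vector<arma::mat> X = to_arma_X(X_list);
  std::vector<arma::ivec> y = to_arma_y(y_list);
  long total = 0;
  for (size_t k = 0; k < X.size(); ++k) total += X[k].n_cols;
  Params G = zeros_like(M);
  double nll = 0.0; int hits = 0;
  for (size_t k = 0; k < X.size(); ++k) {
    if (X[k].n_cols == 0) continue;
    SeqCache S;
    forward_net(M, L, X[k], 0.0, false, S);
    score_cache(S, y[k], nll, hits);
    backward_net(M, L, S, y[k], 1.0 / (double)total, G);
  }
  double loss = nll / (double)total;
  for (size_t p = 0; p < M.size(); ++p) {
    if (l2 > 0 && !is_bias(p, M.size())) {
      loss += 0.5 * l2 * arma::accu(M[p] % M[p]);
      G[p] += l2 * M[p];
    }
  }
  return List::create(Named("loss") = loss, Named("grads") = pack(G));
}
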