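// Minimal LSTM sequence classifier: forward pass, truncated-free BPTT over the
// full window, inverted dropout on the last hidden state, softmax
// cross-entropy, Adam updates, early stopping on a validation split.
//
// Layout conventions
//   X: cube (T time steps) x (C channels) x (n samples), already band-filtered
//      microvolts; per-channel normalisation (mu, sd) is applied on the fly so
//      the big array is never copied.
//   Gates are stacked column-blocks [input | forget | cell | output], each of
//   width H, in W (C x 4H), U (H x 4H), b (1 x 4H).
//
// All randomness (init, shuffling, validation split handled in R, dropout
// masks here) derives from integer seeds, so runs are bit-reproducible on a
// fixed BLAS.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Gather one minibatch time-step matrix (nb x C), normalised.
static void gather_step(const cube& X, const uvec& idx, unsigned t,
                        const vec& mu, const vec& sd, mat& out) {
  const unsigned nb = idx.n_elem, C = X.n_cols;
  for (unsigned c = 0; c < C; ++c) {
    const double m = mu[c], s = sd[c];
    for (unsigned j = 0; j < nb; ++j)
      out(j, c) = (X(t, c, idx[j]) - m) / s;
  }
}

struct Params {
  mat W, U, Wy;
  rowvec b, by;
};

static Params params_from_list(const List& l) {
  Params p;
  p.W  = Rcpp::as<mat>(l["W"]);
  p.U  = Rcpp::as<mat>(l["U"]);
  p.b  = Rcpp::as<rowvec>(l["b"]);
  p.Wy = Rcpp::as<mat>(l["Wy"]);
  p.by = Rcpp::as<rowvec>(l["by"]);
  return p;
}

static List params_to_list(const Params& p) {
  return List::create(Named("W") = p.W, Named("U") = p.U, Named("b") = p.b,
                      Named("Wy") = p.Wy, Named("by") = p.by);
}

// Glorot-uniform initialisation; forget-gate bias starts at 1 so early
// training does not erase the cell state.
// [[Rcpp::export(name = ".lstm_init")]]
List lstm_init_cpp(int n_in, int units, int n_classes, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  const int H = units;
  auto glorot = [&](int r, int c) {
    mat m(r, c);
    const double lim = std::sqrt(6.0 / (r + c));
    for (uword i = 0; i < m.n_elem; ++i) m[i] = lim * unif(rng);
    return m;
  };
  Params p;
  p.W  = glorot(n_in, 4 * H);
  p.U  = glorot(H, 4 * H);
  p.b  = rowvec(4 * H, fill::zeros);
  p.b.cols(H, 2 * H - 1).fill(1.0);
  p.Wy = glorot(H, n_classes);
  p.by = rowvec(n_classes, fill::zeros);
  return params_to_list(p);
}

// Forward over one minibatch; optionally keep gate/state caches for BPTT.
struct Caches {
  cube I, F, G, O, Cc;  // each nb x H x T
  mat h_last;
};

static void forward_batch(const cube& X, const uvec& idx, const Params& p,
                          const vec& mu, const vec& sd, bool keep, Caches& K) {
  const unsigned T = X.n_rows, C = X.n_cols, nb = idx.n_elem;
  const unsigned H = p.U.n_rows;
  mat h(nb, H, fill::zeros), c(nb, H, fill::zeros), Xt(nb, C);
  if (keep) {
    K.I.set_size(nb, H, T); K.F.set_size(nb, H, T); K.G.set_size(nb, H, T);
    K.O.set_size(nb, H, T); K.Cc.set_size(nb, H, T);
  }
  for (unsigned t = 0; t < T; ++t) {
    gather_step(X, idx, t, mu, sd, Xt);
    mat Z = Xt * p.W + h * p.U;
    Z.each_row() += p.b;
    mat I = sigm(Z.cols(0, H - 1));
    mat F = sigm(Z.cols(H, 2 * H - 1));
    mat G = tanh(Z.cols(2 * H, 3 * H - 1));
    mat O = sigm(Z.cols(3 * H, 4 * H - 1));
    c = F % c + I % G;
    h = O % tanh(c);
    if (keep) {
      K.I.slice(t) = I; K.F.slice(t) = F; K.G.slice(t) = G;
      K.O.slice(t) = O; K.Cc.slice(t) = c;
    }
  }
  K.h_last = h;
}

static mat softmax_rows(mat z) {
  z.each_col() -= max(z, 1);
  z = exp(z);
  z.each_col() /= sum(z, 1);
  return z;
}

// Class probabilities for a set of samples (no dropout at inference).
// [[Rcpp::export(name = ".lstm_prob")]]
arma::mat lstm_prob_cpp(const arma::cube& X, const List& params,
                        const arma::vec& mu, const arma::vec& sd,
                        int batch = 256) {
  Params p = params_from_list(params);
  const unsigned n = X.n_slices, K = p.Wy.n_cols;
  mat out(n, K);
  Caches Kc;
  for (unsigned s = 0; s < n; s += batch) {
    const unsigned e = std::min<unsigned>(s + batch, n) - 1;
    uvec idx = regspace<uvec>(s, e);
    forward_batch(X, idx, p, mu, sd, false, Kc);
    mat logits = Kc.h_last * p.Wy;
    logits.each_row() += p.by;
    out.rows(s, e) = softmax_rows(logits);
  }
  return out;
}

struct Adam {
  Params m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  explicit Adam(const Params& p) {
    m.W = zeros(size(p.W)); m.U = zeros(size(p.U)); m.b = zeros<rowvec>(p.b.n_elem);
    m.Wy = zeros(size(p.Wy)); m.by = zeros<rowvec>(p.by.n_elem);
    v = m;
  }
  template <typename M>
  void upd1(M& w, M& mm, M& vv, const M& g, double lr) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * (g % g);
    const double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (mm / c1) / (sqrt(vv / c2) + eps);
  }
  void step(Params& p, const Params& g, double lr) {
    ++t;
    upd1(p.W, m.W, v.W, g.W, lr);
    upd1(p.U, m.U, v.U, g.U, lr);
    upd1(p.b, m.b, v.b, g.b, lr);
    upd1(p.Wy, m.Wy, v.Wy, g.Wy, lr);
    upd1(p.by, m.by, v.by, g.by, lr);
  }
};

static double grad_norm(const Params& g) {
  double s = accu(g.W % g.W) + accu(g.U % g.U) + accu(g.b % g.b) +
             accu(g.Wy % g.Wy) + accu(g.by % g.by);
  return std::sqrt(s);
}

static void scale_params(Params& g, double f) {
  g.W *= f; g.U *= f; g.b *= f; g.Wy *= f; g.by *= f;
}

// Mean cross-entropy and accuracy of probabilities vs 0-based labels.
static void eval_prob(const mat& P, const ivec& y, double& loss, double& acc) {
  const unsigned n = P.n_rows;
  double L = 0; unsigned ok = 0;
  for (unsigned i = 0; i < n; ++i) {
    L += -std::log(std::max(P(i, y[i]), 1e-12));
    uword am; P.row(i).max(am);
    if ((int)am == y[i]) ++ok;
  }
  loss = L / n; acc = (double)ok / n;
}

// Train with Adam + gradient-norm clipping; early stopping on validation
// loss (falls back to training loss when val_idx is empty). Returns the
// best-epoch weights and the per-epoch history.
// [[Rcpp::export(name = ".lstm_fit")]]
List lstm_fit_cpp(const arma::cube& X, const arma::ivec& y,
                  const arma::uvec& train_idx, const arma::uvec& val_idx,
                  const List& init, const arma::vec& mu, const arma::vec& sd,
                  double lr, double dropout, int batch, int max_epochs,
                  int patience, int seed, double clip = 5.0) {
  Params p = params_from_list(init);
  const unsigned H = p.U.n_rows, K = p.Wy.n_cols, C = X.n_cols, T = X.n_rows;
  Adam opt(p);
  std::mt19937_64 rng(static_cast<uint64_t>(seed) ^ 0x9e3779b97f4a7c15ULL);
  std::uniform_real_distribution<double> unif01(0.0, 1.0);

  std::vector<uword> order(train_idx.begin(), train_idx.end());
  std::vector<double> tr_loss, tr_acc, va_loss, va_acc;
  Params best = p;
  double best_val = datum::inf;
  int best_epoch = 0, bad = 0;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0; unsigned ep_ok = 0, ep_n = 0;
    for (size_t s = 0; s < order.size(); s += batch) {
      const size_t e = std::min(s + (size_t)batch, order.size());
      uvec idx(e - s);
      for (size_t j = s; j < e; ++j) idx[j - s] = order[j];
      const unsigned nb = idx.n_elem;

      Caches Kc;
      forward_batch(X, idx, p, mu, sd, true, Kc);

      // dropout on the last hidden state (inverted scaling)
      mat mask(nb, H, fill::ones);
      if (dropout > 0) {
        for (uword i = 0; i < mask.n_elem; ++i)
          mask[i] = unif01(rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
      }
      mat hd = Kc.h_last % mask;
      mat logits = hd * p.Wy;
      logits.each_row() += p.by;
      mat P = softmax_rows(logits);

      for (unsigned j = 0; j < nb; ++j) {
        ep_loss += -std::log(std::max(P(j, y[idx[j]]), 1e-12));
        uword am; P.row(j).max(am);
        if ((int)am == y[idx[j]]) ++ep_ok;
      }
      ep_n += nb;

      // backward
      mat dlog = P;
      for (unsigned j = 0; j < nb; ++j) dlog(j, y[idx[j]]) -= 1.0;
      dlog /= (double)nb;

      Params g;
      g.Wy = hd.t() * dlog;
      g.by = sum(dlog, 0);
      g.W = zeros(size(p.W)); g.U = zeros(size(p.U));
      g.b = zeros<rowvec>(4 * H);

      mat dh = (dlog * p.Wy.t()) % mask;
      mat dc(nb, H, fill::zeros), Xt(nb, C);
      for (int t = T - 1; t >= 0; --t) {
        const mat& I = Kc.I.slice(t); const mat& F = Kc.F.slice(t);
        const mat& G = Kc.G.slice(t); const mat& O = Kc.O.slice(t);
        mat tc = tanh(Kc.Cc.slice(t));
        mat dO = dh % tc;
        dc += dh % O % (1.0 - tc % tc);
        mat cprev = t > 0 ? Kc.Cc.slice(t - 1) : mat(nb, H, fill::zeros);
        mat hprev = t > 0 ? Kc.O.slice(t - 1) % tanh(cprev) : mat(nb, H, fill::zeros);
        mat dI = dc % G, dF = dc % cprev, dG = dc % I;
        mat dZ(nb, 4 * H);
        dZ.cols(0, H - 1)         = dI % I % (1.0 - I);
        dZ.cols(H, 2 * H - 1)     = dF % F % (1.0 - F);
        dZ.cols(2 * H, 3 * H - 1) = dG % (1.0 - G % G);
        dZ.cols(3 * H, 4 * H - 1) = dO % O % (1.0 - O);
        gather_step(X, idx, t, mu, sd, Xt);
        g.W += Xt.t() * dZ;
        g.U += hprev.t() * dZ;
        g.b += sum(dZ, 0);
        dh = dZ * p.U.t();
        dc = dc % F;
      }

      const double gn = grad_norm(g);
      if (gn > clip) scale_params(g, clip / gn);
      opt.step(p, g, lr);
    }
    tr_loss.push_back(ep_loss / ep_n);
    tr_acc.push_back((double)ep_ok / ep_n);

    double vl, va;
    if (val_idx.n_elem > 0) {
      Caches Kc;
      mat P(val_idx.n_elem, K);
      for (unsigned s = 0; s < val_idx.n_elem; s += 256) {
        const unsigned e = std::min<unsigned>(s + 256, val_idx.n_elem) - 1;
        forward_batch(X, val_idx.subvec(s, e), p, mu, sd, false, Kc);
        mat logits = Kc.h_last * p.Wy;
        logits.each_row() += p.by;
        P.rows(s, e) = softmax_rows(logits);
      }
      ivec yv(val_idx.n_elem);
      for (unsigned i = 0; i < val_idx.n_elem; ++i) yv[i] = y[val_idx[i]];
      eval_prob(P, yv, vl, va);
    } else { vl = tr_loss.back(); va = tr_acc.back(); }
    va_loss.push_back(vl); va_acc.push_back(va);

    if (vl < best_val - 1e-6) {
      best_val = vl; best = p; best_epoch = epoch; bad = 0;
    } else if (++bad >= patience) break;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
      Named("params") = params_to_list(best),
      Named("history") = Rcpp::DataFrame::create(
          Named("epoch") = Rcpp::seq_len(tr_loss.size()),
          Named("train_loss") = tr_loss, Named("train_acc") = tr_acc,
          Named("val_loss") = va_loss, Named("val_acc") = va_acc),
      Named("best_epoch") = best_epoch);
}
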