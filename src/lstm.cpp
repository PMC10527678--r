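// Recurrent soft-sensor engine: a single-layer LSTM (ReLU cell activations,
// sigmoid gates) followed by dropout, a ReLU dense layer, dropout, and a
// single output unit whose weights and bias are constrained non-negative.
// Trained with Adam on a modified mean-square loss, with validation-based
// early stopping. Written against Armadillo; batches are processed as
// matrices per timestep (input cube layout: n_windows x n_features x
// n_timesteps).

#include <RcppArmadillo.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <random>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Params {
  mat Wx, Wh, W1, W2;
  rowvec b, b1;
  double b2;
};

Params from_list(const Rcpp::List& p) {
  Params np;
  np.Wx = Rcpp::as<mat>(p["Wx"]);
  np.Wh = Rcpp::as<mat>(p["Wh"]);
  np.b = Rcpp::as<rowvec>(p["b"]);
  np.W1 = Rcpp::as<mat>(p["W1"]);
  np.b1 = Rcpp::as<rowvec>(p["b1"]);
  np.W2 = Rcpp::as<mat>(p["W2"]);
  np.b2 = Rcpp::as<double>(p["b2"]);
  return np;
}

Rcpp::List to_list(const Params& np) {
  return Rcpp::List::create(
      Rcpp::Named("Wx") = np.Wx, Rcpp::Named("Wh") = np.Wh,
      Rcpp::Named("b") = np.b, Rcpp::Named("W1") = np.W1,
      Rcpp::Named("b1") = np.b1, Rcpp::Named("W2") = np.W2,
      Rcpp::Named("b2") = np.b2);
}

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }
inline mat relu(const mat& x) { return clamp(x, 0.0, datum::inf); }

struct Cache {
  cube I, F, G, O, C, H;  // per-timestep activations, each B x H x T
  mat h_last, hdrop, z1, z1drop;
  vec yhat;
};

// Forward pass over a batch; mask1/mask2 are inverted-dropout masks (pass
// empty matrices for inference).
void forward(const Params& np, const cube& X, const mat& mask1,
             const mat& mask2, Cache& cc) {
  const uword B = X.n_rows, T = X.n_slices;
  const uword H = np.Wh.n_rows;
  cc.I.set_size(B, H, T); cc.F.set_size(B, H, T); cc.G.set_size(B, H, T);
  cc.O.set_size(B, H, T); cc.C.set_size(B, H, T); cc.H.set_size(B, H, T);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat A = X.slice(t) * np.Wx + h * np.Wh;
    A.each_row() += np.b;
    mat i = sigmoid(A.cols(0, H - 1));
    mat f = sigmoid(A.cols(H, 2 * H - 1));
    mat g = relu(A.cols(2 * H, 3 * H - 1));
    mat o = sigmoid(A.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % relu(c);
    cc.I.slice(t) = i; cc.F.slice(t) = f; cc.G.slice(t) = g;
    cc.O.slice(t) = o; cc.C.slice(t) = c; cc.H.slice(t) = h;
  }
  cc.h_last = h;
  cc.hdrop = mask1.n_elem ? mat(h % mask1) : h;
  mat z1pre = cc.hdrop * np.W1;
  z1pre.each_row() += np.b1;
  cc.z1 = relu(z1pre);
  cc.z1drop = mask2.n_elem ? mat(cc.z1 % mask2) : cc.z1;
  cc.yhat = cc.z1drop * np.W2 + np.b2;
}

// loss_type 1: mean((|e|+1)^2); loss_type 2: sum(|e|+1)/(2n)
double loss_value(const vec& yhat, const vec& y, int loss_type) {
  vec e = abs(yhat - y);
  if (loss_type == 1) return mean(square(e + 1.0));
  return accu(e + 1.0) / (2.0 * y.n_elem);
}

vec loss_grad(const vec& yhat, const vec& y, int loss_type) {
  vec e = yhat - y;
  vec s = sign(e);
  if (loss_type == 1) return 2.0 * (abs(e) + 1.0) % s / double(y.n_elem);
  return s / (2.0 * y.n_elem);
}

// Backward pass; fills gradients in gr (same shapes as Params).
void backward(const Params& np, const cube& X, const vec& y, int loss_type,
              const mat& mask1, const mat& mask2, const Cache& cc,
              Params& gr) {
  const uword B = X.n_rows, T = X.n_slices;
  const uword H = np.Wh.n_rows;
  vec dy = loss_grad(cc.yhat, y, loss_type);
  gr.W2 = cc.z1drop.t() * dy;
  gr.b2 = accu(dy);
  mat dz1 = dy * np.W2.t();
  if (mask2.n_elem) dz1 %= mask2;
  mat dz1pre = dz1 % conv_to<mat>::from(cc.z1 > 0);
  gr.W1 = cc.hdrop.t() * dz1pre;
  gr.b1 = sum(dz1pre, 0);
  mat dh = dz1pre * np.W1.t();
  if (mask1.n_elem) dh %= mask1;

  gr.Wx.zeros(np.Wx.n_rows, np.Wx.n_cols);
  gr.Wh.zeros(np.Wh.n_rows, np.Wh.n_cols);
  gr.b.zeros(np.b.n_elem);
  mat dc(B, H, fill::zeros);
  for (uword t = T; t-- > 0;) {
    const mat& i = cc.I.slice(t);
    const mat& f = cc.F.slice(t);
    const mat& g = cc.G.slice(t);
    const mat& o = cc.O.slice(t);
    const mat& c = cc.C.slice(t);
    mat hc = relu(c);
    mat cprev = (t == 0) ? mat(B, H, fill::zeros) : cc.C.slice(t - 1);
    mat hprev = (t == 0) ? mat(B, H, fill::zeros) : cc.H.slice(t - 1);
    mat do_ = dh % hc;
    dc += dh % o % conv_to<mat>::from(c > 0);
    mat dAi = dc % g % i % (1.0 - i);
    mat dAf = dc % cprev % f % (1.0 - f);
    mat dAg = dc % i % conv_to<mat>::from(g > 0);
    mat dAo = do_ % o % (1.0 - o);
    mat dA = join_rows(dAi, dAf, dAg, dAo);
    gr.Wx += X.slice(t).t() * dA;
    gr.Wh += hprev.t() * dA;
    gr.b += sum(dA, 0);
    dh = dA * np.Wh.t();
    dc %= f;
  }
}

struct Adam {
  Params m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  long step = 0;
  void init(const Params& np) {
    m.Wx.zeros(size(np.Wx)); m.Wh.zeros(size(np.Wh));
    m.b.zeros(np.b.n_elem); m.W1.zeros(size(np.W1));
    m.b1.zeros(np.b1.n_elem); m.W2.zeros(size(np.W2)); m.b2 = 0;
    v = m;
  }
  template <typename T>
  void upd(T& p, T& mm, T& vv, const T& g, double lr) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * (g % g);
    T mhat = mm / (1 - std::pow(b1, step));
    T vhat = vv / (1 - std::pow(b2, step));
    p -= lr * mhat / (sqrt(vhat) + eps);
  }
  void update(Params& np, const Params& g, double lr) {
    ++step;
    upd(np.Wx, m.Wx, v.Wx, g.Wx, lr);
    upd(np.Wh, m.Wh, v.Wh, g.Wh, lr);
    upd(np.b, m.b, v.b, g.b, lr);
    upd(np.W1, m.W1, v.W1, g.W1, lr);
    upd(np.b1, m.b1, v.b1, g.b1, lr);
    upd(np.W2, m.W2, v.W2, g.W2, lr);
    double gm = m.b2 = b1 * m.b2 + (1 - b1) * g.b2;
    double gv = v.b2 = b2 * v.b2 + (1 - b2) * g.b2 * g.b2;
    np.b2 -= lr * (gm / (1 - std::pow(b1, step))) /
             (std::sqrt(gv / (1 - std::pow(b2, step))) + eps);
  }
};

cube rows_of(const cube& X, const uvec& idx) {
  cube out(idx.n_elem, X.n_cols, X.n_slices);
  for (uword t = 0; t < X.n_slices; ++t) out.slice(t) = X.slice(t).rows(idx);
  return out;
}

}  // namespace

// [[Rcpp::export]]
arma::vec cpp_lstm_predict(Rcpp::List params, arma::cube X) {
  Params np = from_list(params);
  Cache cc;
  mat empty;
  forward(np, X, empty, empty, cc);
  return cc.yhat;
}

// Analytic gradients for one batch (no dropout); used by the
// finite-difference gradient checks in the test suite.
// [[Rcpp::export]]
Rcpp::List cpp_lstm_grad(Rcpp::List params, arma::cube X, arma::vec y,
                         int loss_type) {
  Params np = from_list(params), gr;
  Cache cc;
  mat empty;
  forward(np, X, empty, empty, cc);
  backward(np, X, y, loss_type, empty, empty, cc, gr);
  Rcpp::List g = to_list(gr);
  g["loss"] = loss_value(cc.yhat, y, loss_type);
  return g;
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_train(Rcpp::List params, arma::cube X, arma::vec y,
                          arma::cube Xval, arma::vec yval, Rcpp::List opts) {
  Params np = from_list(params);
  const double lr = Rcpp::as<double>(opts["learning_rate"]);
  const int max_epochs = Rcpp::as<int>(opts["max_epochs"]);
  const int batch_size = Rcpp::as<int>(opts["batch_size"]);
  const double dropout = Rcpp::as<double>(opts["dropout_rate"]);
  const int patience = Rcpp::as<int>(opts["patience"]);
  const int loss_type = Rcpp::as<int>(opts["loss_type"]);
  const unsigned int seed = Rcpp::as<unsigned int>(opts["seed"]);
  const uword n = X.n_rows;
  const uword H = np.Wh.n_rows, D = np.W1.n_cols;
  const bool has_val = Xval.n_rows > 0;

  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double keep = 1.0 - dropout;

  Adam adam;
  adam.init(np);
  Params best = np, gr;
  double best_val = datum::inf;
  int wait = 0, best_epoch = 0, epoch = 0;
  std::vector<double> hist_train, hist_val;
  Cache cc;
  mat empty;

  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    // epoch shuffle
    uvec perm(n);
    std::iota(perm.begin(), perm.end(), 0);
    std::shuffle(perm.begin(), perm.end(), rng);
    double ep_loss = 0.0;
    uword nb = 0;
    for (uword start = 0; start < n; start += batch_size) {
      uword stop_ = std::min<uword>(start + batch_size, n) - 1;
      uvec idx = perm.subvec(start, stop_);
      cube Xb = rows_of(X, idx);
      vec yb = y.elem(idx);
      mat m1, m2;
      if (dropout > 0) {
        m1.set_size(idx.n_elem, H);
        m2.set_size(idx.n_elem, D);
        for (auto& e : m1) e = (unif(rng) < keep) ? 1.0 / keep : 0.0;
        for (auto& e : m2) e = (unif(rng) < keep) ? 1.0 / keep : 0.0;
      }
      forward(np, Xb, m1, m2, cc);
      double l = loss_value(cc.yhat, yb, loss_type);
      if (!std::isfinite(l))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", epoch);
      ep_loss += l;
      ++nb;
      backward(np, Xb, yb, loss_type, m1, m2, cc, gr);
      adam.update(np, gr, lr);
      // non-negativity constraints on the output layer
      np.W2 = clamp(np.W2, 0.0, datum::inf);
      if (np.b2 < 0) np.b2 = 0;
    }
    hist_train.push_back(ep_loss / nb);
    double vl;
    if (has_val) {
      forward(np, Xval, empty, empty, cc);
      vl = loss_value(cc.yhat, yval, loss_type);
    } else {
      vl = ep_loss / nb;
    }
    if (!std::isfinite(vl))
      Rcpp::stop("training diverged (non-finite validation loss) at epoch %d",
                 epoch);
    hist_val.push_back(vl);
    if (vl < best_val) {
      best_val = vl;
      best = np;
      best_epoch = epoch;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
  }

  Rcpp::List out = to_list(best);
  out["train_loss"] = hist_train;
  out["val_loss"] = hist_val;
  out["best_epoch"] = best_epoch;
  out["stopped_epoch"] = std::min(epoch, max_epochs);
  out["best_val_loss"] = best_val;
  return out;
}
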