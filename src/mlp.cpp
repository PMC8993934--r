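// Feed-forward stress network trained by minimising 1 - KGE.
//
// The Kling-Gupta efficiency is a set-level score, so the mini-batch
// gradient is the analytic derivative of 1 - KGE over the whole batch with
// respect to each prediction. All randomness (weight init, shuffling,
// dropout masks) is drawn from R's RNG so set.seed() on the R side makes
// training fully reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static inline mat relu(const mat& x) {
  return arma::clamp(x, 0.0, arma::datum::inf);
}

static inline mat sigmoid(const mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// 1 - KGE of pred against target (sample sd, r := 0 for constant pred).
// Returns NA when the target scope is degenerate.
static double kge_loss(const vec& pred, const vec& target) {
  const double n = static_cast<double>(target.n_elem);
  if (n < 2) return NA_REAL;
  const double mt = arma::mean(target), mp = arma::mean(pred);
  const double st = arma::stddev(target), sp = arma::stddev(pred);
  if (st <= 0.0 || mt == 0.0) return NA_REAL;
  double r = 0.0;
  if (sp > 0.0) {
    r = arma::dot(pred - mp, target - mt) / ((n - 1.0) * sp * st);
  }
  const double a = sp / st, b = mp / mt;
  const double D = (r - 1.0) * (r - 1.0) + (a - 1.0) * (a - 1.0) +
                   (b - 1.0) * (b - 1.0);
  return std::sqrt(D);
}

// dL/dpred for L = 1 - KGE(pred, target); zero vector when degenerate.
static vec kge_grad(const vec& pred, const vec& target) {
  const double n = static_cast<double>(target.n_elem);
  const double mt = arma::mean(target), mp = arma::mean(pred);
  const double st = arma::stddev(target), sp = arma::stddev(pred);
  vec g(pred.n_elem, arma::fill::zeros);
  if (st <= 1e-12 || std::abs(mt) <= 1e-12 || sp <= 1e-12) return g;
  const vec dp = pred - mp, dt = target - mt;
  const double r = arma::dot(dp, dt) / ((n - 1.0) * sp * st);
  const double a = sp / st, b = mp / mt;
  const double D = (r - 1.0) * (r - 1.0) + (a - 1.0) * (a - 1.0) +
                   (b - 1.0) * (b - 1.0);
  if (D < 1e-15) return g;
  const double L = std::sqrt(D);
  const vec dr = dt / ((n - 1.0) * sp * st) - r * dp / ((n - 1.0) * sp * sp);
  const vec da = dp / ((n - 1.0) * sp * st);
  const double db = 1.0 / (n * mt);
  g = ((r - 1.0) * dr + (a - 1.0) * da + (b - 1.0) * db) / L;
  return g;
}

struct Net {
  std::vector<mat> W;
  std::vector<vec> b;
};

// forward pass without dropout; rows of X are samples
static vec net_forward(const Net& net, const mat& X) {
  mat a = X;
  const size_t L = net.W.size();
  for (size_t l = 0; l + 1 < L; ++l) {
    a = relu(a * net.W[l] + arma::repmat(net.b[l].t(), a.n_rows, 1));
  }
  mat z = a * net.W[L - 1] + arma::repmat(net.b[L - 1].t(), a.n_rows, 1);
  return vec(sigmoid(z));
}

// Fisher-Yates shuffle driven by R's RNG
static arma::uvec r_shuffle(size_t n) {
  arma::uvec idx = arma::regspace<arma::uvec>(0, n - 1);
  for (size_t i = n - 1; i > 0; --i) {
    size_t j = static_cast<size_t>(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

// [[Rcpp::export(name = ".mlp_train_cpp")]]
List mlp_train_cpp(const arma::mat& X, const arma::vec& y,
                   const arma::mat& Xval, const arma::vec& yval,
                   const IntegerVector& hidden,
                   double lr, int batch_size, int max_epochs,
                   double dropout, int patience) {
  const size_t n = X.n_rows, d = X.n_cols;
  const size_t nh = hidden.size();

  // layer sizes: d -> hidden... -> 1
  std::vector<size_t> sizes;
  sizes.push_back(d);
  for (size_t l = 0; l < nh; ++l) sizes.push_back(hidden[l]);
  sizes.push_back(1);
  const size_t L = sizes.size() - 1;

  Net net;
  std::vector<mat> mW(L), vW(L);
  std::vector<vec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    const size_t fin = sizes[l], fout = sizes[l + 1];
    // He init for ReLU layers, Glorot-like for the sigmoid output
    const double sdw = (l + 1 < L) ? std::sqrt(2.0 / fin)
                                   : std::sqrt(1.0 / fin);
    mat W(fin, fout);
    for (size_t i = 0; i < fin; ++i)
      for (size_t j = 0; j < fout; ++j)
        W(i, j) = norm_rand() * sdw;
    net.W.push_back(W);
    net.b.push_back(vec(fout, arma::fill::zeros));
    mW[l] = mat(fin, fout, arma::fill::zeros);
    vW[l] = mat(fin, fout, arma::fill::zeros);
    mb[l] = vec(fout, arma::fill::zeros);
    vb[l] = vec(fout, arma::fill::zeros);
  }

  const double beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8;
  long tstep = 0;

  mat hist(max_epochs, 2);
  hist.fill(NA_REAL);
  double best_val = arma::datum::inf;
  Net best = net;
  int wait = 0, epochs_run = 0;
  bool diverged = false;

  for (int ep = 0; ep < max_epochs; ++ep) {
    arma::uvec order = r_shuffle(n);
    for (size_t start = 0; start < n; start += batch_size) {
      const size_t stop = std::min(n, start + batch_size);
      if (stop - start < 2) continue;  // KGE undefined on a single point
      arma::uvec bidx = order.subvec(start, stop - 1);
      mat a = X.rows(bidx);
      vec yb = y.elem(bidx);

      // forward with inverted dropout on hidden activations
      std::vector<mat> acts;   // post-activation (after dropout), acts[0]=input
      std::vector<mat> zs;     // pre-activations
      std::vector<mat> masks;  // dropout masks (scaled)
      acts.push_back(a);
      for (size_t l = 0; l + 1 < L; ++l) {
        mat z = acts[l] * net.W[l] + arma::repmat(net.b[l].t(), a.n_rows, 1);
        zs.push_back(z);
        mat h = relu(z);
        mat m(h.n_rows, h.n_cols, arma::fill::ones);
        if (dropout > 0.0) {
          for (arma::uword i = 0; i < m.n_elem; ++i)
            m[i] = (unif_rand() < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
          h %= m;
        }
        masks.push_back(m);
        acts.push_back(h);
      }
      mat zout = acts[L - 1] * net.W[L - 1] +
                 arma::repmat(net.b[L - 1].t(), a.n_rows, 1);
      vec pred = vec(sigmoid(zout));

      vec g = kge_grad(pred, yb);
      if (!g.is_finite()) { diverged = true; break; }

      // backprop
      mat delta = g % pred % (1.0 - pred);  // n x 1
      ++tstep;
      const double bc1 = 1.0 - std::pow(beta1, (double)tstep);
      const double bc2 = 1.0 - std::pow(beta2, (double)tstep);
      for (int l = (int)L - 1; l >= 0; --l) {
        mat dW = acts[l].t() * delta;
        vec db = arma::sum(delta, 0).t();
        if (l > 0) {
          mat da = delta * net.W[l].t();
          da %= masks[l - 1];
          delta = da % arma::conv_to<mat>::from(zs[l - 1] > 0.0);
        }
        mW[l] = beta1 * mW[l] + (1.0 - beta1) * dW;
        vW[l] = beta2 * vW[l] + (1.0 - beta2) * arma::square(dW);
        mb[l] = beta1 * mb[l] + (1.0 - beta1) * db;
        vb[l] = beta2 * vb[l] + (1.0 - beta2) * arma::square(db);
        net.W[l] -= lr * (mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + adam_eps);
        net.b[l] -= lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + adam_eps);
      }
    }
    if (diverged) break;

    const double tr_loss = kge_loss(net_forward(net, X), y);
    const double va_loss = kge_loss(net_forward(net, Xval), yval);
    hist(ep, 0) = tr_loss;
    hist(ep, 1) = va_loss;
    epochs_run = ep + 1;
    if (!R_finite(tr_loss) || !R_finite(va_loss)) { diverged = true; break; }

    if (va_loss < best_val - 1e-6) {
      best_val = va_loss;
      best = net;
      wait = 0;
    } else if (++wait >= patience) {
      break;  // validation objective stopped improving
    }
  }

  List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) {
    Wout[l] = wrap(best.W[l]);
    bout[l] = wrap(best.b[l]);
  }
  return List::create(
    _["weights"] = Wout,
    _["biases"] = bout,
    _["history"] = wrap(hist.rows(0, std::max(0, epochs_run - 1))),
    _["best_val_loss"] = best_val,
    _["epochs_run"] = epochs_run,
    _["diverged"] = diverged);
}

// [[Rcpp::export(name = ".mlp_predict_cpp")]]
arma::vec mlp_predict_cpp(const arma::mat& X, const List& weights,
                          const List& biases) {
  Net net;
  const size_t L = weights.size();
  for (size_t l = 0; l < L; ++l) {
    net.W.push_back(as<mat>(weights[l]));
    net.b.push_back(as<vec>(biases[l]));
  }
  return net_forward(net, X);
}
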