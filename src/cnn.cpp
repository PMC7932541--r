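// 1-D convolutional binary classifier on strand-doubled one-hot DNA.
//
// Input per sample: 200 integer codes in {-1,0,1,2,3,4} where 0..4 index the
// one-hot columns (null,a,t,c,g) and -1 denotes an occluded (all-zero) row.
// One-hot expansion happens here, batch by batch, so the corpus is only ever
// held as integer codes.
//
// Architecture: conv(F filters, kernel k, ReLU) -> max-pool(2) ->
// conv(F, k, ReLU) -> global max-pool -> dense(D, ReLU) -> dropout ->
// dense(1, sigmoid).  Binary cross-entropy loss, Adam updates.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Weights {
  arma::mat W1; arma::vec b1;
  arma::mat W2; arma::vec b2;
  arma::mat W3; arma::vec b3;
  arma::vec W4; double b4;
  int k1, k2, F, D;
};

Weights parse_weights(const List& w) {
  Weights x;
  x.W1 = as<arma::mat>(w["W1"]); x.b1 = as<arma::vec>(w["b1"]);
  x.W2 = as<arma::mat>(w["W2"]); x.b2 = as<arma::vec>(w["b2"]);
  x.W3 = as<arma::mat>(w["W3"]); x.b3 = as<arma::vec>(w["b3"]);
  x.W4 = as<arma::vec>(w["W4"]); x.b4 = as<double>(w["b4"]);
  x.F = x.W1.n_cols;
  x.k1 = x.W1.n_rows / 5;
  x.k2 = x.W2.n_rows / x.F;
  x.D = x.W3.n_cols;
  if ((int)x.W1.n_rows != 5 * x.k1 || (int)x.W2.n_rows != x.k2 * x.F)
    stop("inconsistent weight dimensions");
  return x;
}

List weights_to_list(const Weights& x) {
  return List::create(_["W1"] = x.W1, _["b1"] = x.b1,
                      _["W2"] = x.W2, _["b2"] = x.b2,
                      _["W3"] = x.W3, _["b3"] = x.b3,
                      _["W4"] = x.W4, _["b4"] = x.b4);
}

// intermediates kept for backprop
struct Cache {
  arma::mat M1, H1, P, M2, H2;
  arma::umat argp;           // pooled-from row index per (pool pos, filter)
  arma::uvec argg;           // global-max row index per filter
  arma::vec g, dpre, d, mask;
  double z, p;
};

// forward pass for one sample; codes has length 200
double forward_one(const Weights& w, const int* codes, int len, Cache* cache,
                   const arma::vec* dropout_mask) {
  const int L1 = len - w.k1 + 1;
  const int L2 = L1 / 2;
  const int L3 = L2 - w.k2 + 1;
  if (L3 < 1) stop("sequence too short for kernel size");

  arma::mat M1(L1, 5 * w.k1, arma::fill::zeros);
  for (int i = 0; i < L1; ++i)
    for (int a = 0; a < w.k1; ++a) {
      int c = codes[i + a];
      if (c >= 0) M1(i, a * 5 + c) = 1.0;
    }
  arma::mat H1 = M1 * w.W1;
  H1.each_row() += w.b1.t();
  H1.transform([](double v) { return v > 0 ? v : 0.0; });

  arma::mat P(L2, w.F);
  arma::umat argp(L2, w.F);
  for (int j = 0; j < L2; ++j)
    for (int f = 0; f < w.F; ++f) {
      double a0 = H1(2 * j, f), a1 = H1(2 * j + 1, f);
      if (a0 >= a1) { P(j, f) = a0; argp(j, f) = 2 * j; }
      else          { P(j, f) = a1; argp(j, f) = 2 * j + 1; }
    }

  arma::mat M2(L3, w.k2 * w.F);
  for (int i = 0; i < L3; ++i)
    for (int a = 0; a < w.k2; ++a)
      for (int f = 0; f < w.F; ++f)
        M2(i, a * w.F + f) = P(i + a, f);
  arma::mat H2 = M2 * w.W2;
  H2.each_row() += w.b2.t();
  H2.transform([](double v) { return v > 0 ? v : 0.0; });

  arma::vec g(w.F);
  arma::uvec argg(w.F);
  for (int f = 0; f < w.F; ++f) {
    arma::uword idx;
    g(f) = H2.col(f).max(idx);
    argg(f) = idx;
  }

  arma::vec dpre = w.W3.t() * g + w.b3;
  arma::vec d = dpre;
  d.transform([](double v) { return v > 0 ? v : 0.0; });
  if (dropout_mask) d %= *dropout_mask;

  double z = arma::dot(w.W4, d) + w.b4;
  double p = 1.0 / (1.0 + std::exp(-z));

  if (cache) {
    cache->M1 = std::move(M1); cache->H1 = std::move(H1);
    cache->P = std::move(P);   cache->argp = std::move(argp);
    cache->M2 = std::move(M2); cache->H2 = std::move(H2);
    cache->argg = std::move(argg); cache->g = std::move(g);
    cache->dpre = std::move(dpre); cache->d = std::move(d);
    cache->mask = dropout_mask ? *dropout_mask
                               : arma::vec(w.D, arma::fill::ones);
    cache->z = z; cache->p = p;
  }
  return p;
}

struct Grads {
  arma::mat W1, W2, W3;
  arma::vec b1, b2, b3, W4;
  double b4;
  void zero_like(const Weights& w) {
    W1.zeros(arma::size(w.W1)); b1.zeros(arma::size(w.b1));
    W2.zeros(arma::size(w.W2)); b2.zeros(arma::size(w.b2));
    W3.zeros(arma::size(w.W3)); b3.zeros(arma::size(w.b3));
    W4.zeros(arma::size(w.W4)); b4 = 0.0;
  }
  void scale(double s) {
    W1 *= s; b1 *= s; W2 *= s; b2 *= s; W3 *= s; b3 *= s; W4 *= s; b4 *= s;
  }
};

// accumulate gradient of BCE loss for one sample into g
void backward_one(const Weights& w, const Cache& c, double y, Grads& gr) {
  const double dz = c.p - y;

  gr.W4 += c.d * dz;
  gr.b4 += dz;

  arma::vec dd = w.W4 * dz;
  dd %= c.mask;
  for (int i = 0; i < w.D; ++i) if (c.dpre(i) <= 0) dd(i) = 0.0;

  gr.W3 += c.g * dd.t();
  gr.b3 += dd;
  arma::vec dg = w.W3 * dd;

  arma::mat dH2(c.H2.n_rows, w.F, arma::fill::zeros);
  for (int f = 0; f < w.F; ++f)
    if (c.H2(c.argg(f), f) > 0) dH2(c.argg(f), f) = dg(f);

  gr.W2 += c.M2.t() * dH2;
  gr.b2 += dH2.t() * arma::ones(dH2.n_rows);

  arma::mat dM2 = dH2 * w.W2.t();  // L3 x k2*F
  const int L3 = dM2.n_rows, L2 = c.P.n_rows;
  arma::mat dP(L2, w.F, arma::fill::zeros);
  for (int i = 0; i < L3; ++i)
    for (int a = 0; a < w.k2; ++a)
      for (int f = 0; f < w.F; ++f)
        dP(i + a, f) += dM2(i, a * w.F + f);

  arma::mat dH1(c.H1.n_rows, w.F, arma::fill::zeros);
  for (int j = 0; j < L2; ++j)
    for (int f = 0; f < w.F; ++f) {
      arma::uword src = c.argp(j, f);
      if (c.H1(src, f) > 0) dH1(src, f) += dP(j, f);
    }

  gr.W1 += c.M1.t() * dH1;
  gr.b1 += dH1.t() * arma::ones(dH1.n_rows);
}

double bce(double p, double y) {
  const double eps = 1e-12;
  p = std::min(std::max(p, eps), 1.0 - eps);
  return -(y * std::log(p) + (1.0 - y) * std::log(1.0 - p));
}

void adam_update(arma::mat& w, arma::mat& m, arma::mat& v, const arma::mat& g,
                 double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  arma::mat mhat = m / (1 - std::pow(b1, t));
  arma::mat vhat = v / (1 - std::pow(b2, t));
  w -= lr * mhat / (arma::sqrt(vhat) + eps);
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_cnn_predict(List weights, IntegerMatrix codes) {
  Weights w = parse_weights(weights);
  const int n = codes.nrow(), len = codes.ncol();
  NumericVector out(n);
  std::vector<int> row(len);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < len; ++j) row[j] = codes(i, j);
    out[i] = forward_one(w, row.data(), len, nullptr, nullptr);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_cnn_loss_grad(List weights, IntegerMatrix codes, NumericVector labels) {
  Weights w = parse_weights(weights);
  const int n = codes.nrow(), len = codes.ncol();
  Grads gr; gr.zero_like(w);
  double loss = 0.0;
  std::vector<int> row(len);
  Cache cache;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < len; ++j) row[j] = codes(i, j);
    forward_one(w, row.data(), len, &cache, nullptr);
    loss += bce(cache.p, labels[i]);
    backward_one(w, cache, labels[i], gr);
  }
  gr.scale(1.0 / n);
  return List::create(
      _["loss"] = loss / n,
      _["grads"] = List::create(_["W1"] = gr.W1, _["b1"] = gr.b1,
                                _["W2"] = gr.W2, _["b2"] = gr.b2,
                                _["W3"] = gr.W3, _["b3"] = gr.b3,
                                _["W4"] = gr.W4, _["b4"] = gr.b4));
}

// One pass over the training data in batches.  `order` is a 0-based
// permutation of sample indices (drawn R-side so the shuffle is governed by
// R's RNG); `seed` drives the dropout masks only.
// [[Rcpp::export]]
List cpp_cnn_train_epoch(List weights, List adam, IntegerMatrix codes,
                         NumericVector labels, IntegerVector order,
                         int batch_size, double lr, double dropout, int seed) {
  Weights w = parse_weights(weights);
  const int n = order.size(), len = codes.ncol();

  arma::mat mW1 = as<arma::mat>(adam["mW1"]), vW1 = as<arma::mat>(adam["vW1"]);
  arma::mat mW2 = as<arma::mat>(adam["mW2"]), vW2 = as<arma::mat>(adam["vW2"]);
  arma::mat mW3 = as<arma::mat>(adam["mW3"]), vW3 = as<arma::mat>(adam["vW3"]);
  arma::vec mb1 = as<arma::vec>(adam["mb1"]), vb1 = as<arma::vec>(adam["vb1"]);
  arma::vec mb2 = as<arma::vec>(adam["mb2"]), vb2 = as<arma::vec>(adam["vb2"]);
  arma::vec mb3 = as<arma::vec>(adam["mb3"]), vb3 = as<arma::vec>(adam["vb3"]);
  arma::vec mW4 = as<arma::vec>(adam["mW4"]), vW4 = as<arma::vec>(adam["vW4"]);
  double mb4 = as<double>(adam["mb4"]), vb4 = as<double>(adam["vb4"]);
  double t = as<double>(adam["t"]);

  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double keep = 1.0 - dropout;

  double loss_sum = 0.0;
  std::vector<int> row(len);
  Cache cache;
  Grads gr;

  for (int start = 0; start < n; start += batch_size) {
    const int stop_ = std::min(start + batch_size, n);
    const int bs = stop_ - start;
    gr.zero_like(w);
    for (int bi = start; bi < stop_; ++bi) {
      const int i = order[bi];
      for (int j = 0; j < len; ++j) row[j] = codes(i, j);
      arma::vec mask(w.D);
      if (dropout > 0) {
        for (int u = 0; u < w.D; ++u)
          mask(u) = unif(rng) < keep ? 1.0 / keep : 0.0;
      } else {
        mask.ones();
      }
      forward_one(w, row.data(), len, &cache, &mask);
      loss_sum += bce(cache.p, labels[i]);
      backward_one(w, cache, labels[i], gr);
    }
    gr.scale(1.0 / bs);
    t += 1.0;
    adam_update(w.W1, mW1, vW1, gr.W1, lr, t);
    adam_update(w.W2, mW2, vW2, gr.W2, lr, t);
    adam_update(w.W3, mW3, vW3, gr.W3, lr, t);
    { arma::mat m(mb1), v(vb1), g(gr.b1), ww(w.b1);
      adam_update(ww, m, v, g, lr, t); w.b1 = ww; mb1 = m; vb1 = v; }
    { arma::mat m(mb2), v(vb2), g(gr.b2), ww(w.b2);
      adam_update(ww, m, v, g, lr, t); w.b2 = ww; mb2 = m; vb2 = v; }
    { arma::mat m(mb3), v(vb3), g(gr.b3), ww(w.b3);
      adam_update(ww, m, v, g, lr, t); w.b3 = ww; mb3 = m; vb3 = v; }
    { arma::mat m(mW4), v(vW4), g(gr.W4), ww(w.W4);
      adam_update(ww, m, v, g, lr, t); w.W4 = ww; mW4 = m; vW4 = v; }
    {
      const double bb1 = 0.9, bb2 = 0.999, eps = 1e-8;
      mb4 = bb1 * mb4 + (1 - bb1) * gr.b4;
      vb4 = bb2 * vb4 + (1 - bb2) * gr.b4 * gr.b4;
      w.b4 -= lr * (mb4 / (1 - std::pow(bb1, t))) /
              (std::sqrt(vb4 / (1 - std::pow(bb2, t))) + eps);
    }
  }

  List adam_out = List::create(
      _["mW1"] = mW1, _["vW1"] = vW1, _["mb1"] = mb1, _["vb1"] = vb1,
      _["mW2"] = mW2, _["vW2"] = vW2, _["mb2"] = mb2, _["vb2"] = vb2,
      _["mW3"] = mW3, _["vW3"] = vW3, _["mb3"] = mb3, _["vb3"] = vb3,
      _["mW4"] = mW4, _["vW4"] = vW4, _["mb4"] = mb4, _["vb4"] = vb4,
      _["t"] = t);
  return List::create(_["weights"] = weights_to_list(w),
                      _["adam"] = adam_out,
                      _["loss"] = loss_sum / n);
}
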